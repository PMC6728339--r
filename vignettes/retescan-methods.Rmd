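---
title: "Methods: gene overlaps, Shine-Dalgarno energetics, and start re-annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene overlaps, Shine-Dalgarno energetics, and start re-annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retescan)
```

# Scope and model

`retescan` asks, for an annotated prokaryotic genome, how much of its gene
organization is compatible with translational coupling by
termination–reinitiation: how many co-directional gene pairs overlap at
their stop/start codons, how many genes are "leading" (so far from any
upstream co-directional gene that initiation must be de novo), and how both
sets use the Shine-Dalgarno (SD) signal, judged by hybridization free
energy against the 16S rRNA anti-SD. A second, independent stage improves
the start-codon annotation, on which all distance measurements depend, from
alignments of homologous proteins.

All internal coordinates are 0-based half-open on the forward strand;
GenBank/GFF3 conventions are converted only at the I/O boundary. This makes
every distance a plain difference: on the plus strand the intergenic
distance is `downstream$start - upstream$end`, on the minus strand
`upstream$start - downstream$end`. Zero means directly adjacent codons;
`ATGA` gives −4 and `TGATG` −1.

# Distance classification

Co-directional pairs are consecutive same-strand CDS in translation order;
an opposite-strand gene in between does not break the pair, and each gene
is downstream in at most one pair. The five classes are: `overlapping`
(*d* < 0), `close10` (0–9 nt), `medium50` (10–50 nt), and for *d* > 50 nt
`far` or `lead` depending on whether an opposite-strand gene start falls
inside the gap ("start" meaning the forward-strand coordinate of the first
base of its start codon, strictly inside the half-open gap interval).

Two deliberate choices here were genuinely open:

* **Distance 0.** The five-class scheme skips adjacency (classes are
  "negative" and "1–9 nt"). We assign 0 to `close10` by default, because a
  zero-length gap behaves like a short gap for reinitiation; setting
  `distance_config(adjacent_class = "own_class")` reports a separate
  `adjacent` class instead.
* **Two leading-gene notions.** The `lead` distance class (> 50 nt plus an
  opposite-strand start) and the statistical "leading gene" set (≥ 200 nt
  from the upstream gene end, or no upstream gene on the contig) are both
  kept, under different names, rather than silently merged: the former is a
  pair label, the latter — configurable via `leading_gene_min_gap`, default
  200 nt — is the de novo initiation reference set used in all SD
  statistics.

Nested genes (a downstream gene entirely inside its upstream partner)
receive no special case: their distance is negative and they classify as
overlapping. Pairs never wrap across the origin of circular contigs, and
origin-spanning genes (GenBank `join` locations) are excluded on input with
a warning; both situations affect at most one junction per strand.

# SD energetics

The anti-SD is found by scanning the 3′ tail of the annotated 16S rRNA
(final 13 nt by default; configurable, since only "the 3′ end" is
biologically fixed) for the minimum-mismatch match to the canonical
`ACCUCC`, breaking ties toward the 3′ terminus where the biological
anti-SD sits, then extending by 1 nt on each side to 8 nt (padding from the
16S body if the tail window is exceeded on the 5′ side; clipping, with a
warning, past the 3′ terminus).

Each CDS is scored on the 12 nt strictly upstream of its start codon
(positions −12…−1 on the coding strand; pairing is not allowed to spill
into the start codon). Windows that are absent — less than 12 nt of flank
on a linear contig — or that contain ambiguity codes are classed `none`
rather than guessed, because the energy model is defined on A/C/G/U only.
Circular contigs wrap.

The energy model is a nearest-neighbor RNA:RNA duplex restricted to
contiguous helices: no bulges, internal loops, or dangling ends.

$$\Delta G = \Delta G_{\mathrm{init}} + \sum_{\text{steps}} \Delta G_{\mathrm{stack}} + \sum_{\text{helix ends}} \Delta G_{\mathrm{AU/GU}}$$

minimized over every registration and every sub-helix of the two strands,
with 0 returned when no duplex is favorable. Parameters (kcal/mol at
37 °C) live in a versioned TSV (`inst/extdata/nn_params.tsv`): Watson-Crick
stacks of Xia et al. 1998, GU wobble stacks per the Turner rules,
initiation +4.09, terminal AU/GU penalty +0.45, so alternates can be
swapped without code changes. The minimization is a dynamic program over
pair positions; an independent brute-force enumeration of all helix
placements exists in the test suite and must agree exactly on seeded random
sequence pairs. Two non-obvious facts the tests encode: reading the duplex
from its other end corresponds to *swapping* the strands (reversing a
string would change the molecule, since 5′→3′ direction is part of its
identity), and with wobble enabled a single substitution can legitimately
beat the perfect Watson-Crick complement (some GU stacks, e.g. 5′GU/3′CG
at −2.5, are stronger than the WC stack they replace), so the
complement-optimality property is asserted only for the WC-only model.

Classification uses the strict thresholds ΔG < −3.5 kcal/mol (`sd`) and
ΔG < −8.4 kcal/mol (`strong_sd`); the boundary values themselves classify
into the weaker class, and undefined energies into `none`.

# Start re-annotation

Start codons are often mis-annotated because start codons also encode
ordinary residues; start *positions*, however, are conserved. The
re-annotation stage:

1. clusters proteins greedily at 90% identity (sequences sorted by length,
   each joining the first cluster whose founding representative it matches,
   else founding its own), selects representatives (all reference-set
   members, else the longest member), re-clusters representatives at 50%,
   and discards loose clusters without reference-set members;
2. keeps a query only if *strictly more than* 10 non-identical homologs
   qualify, taking the 10 best;
3. scans the query + 10-homolog alignment with a 3-column sliding window,
   counting homolog (never query) start columns; windows with support ≥ 5
   qualify, and among them the window closest to the query's annotated
   start column is selected, then the column inside it with the most
   homolog starts (ties toward the query start column). This two-step
   reading — qualify by support, then choose by proximity — is our
   resolution of an ambiguous consensus rule and is isolated in
   `scan_consensus_start()` for easy revision;
4. maps the consensus column to a codon offset (query residues counted
   skipping gaps downstream of the query start; raw columns upstream,
   where the query row is all gaps) and moves the start to the in-frame
   start codon *closest to the original annotation* within the span
   between annotation and consensus — minimizing the sequence extension
   when the consensus is upstream, the residue loss when downstream —
   leaving the annotation unchanged when no start codon exists there.

Identity is defined as matches / alignment columns of a global alignment
(end gaps count against identity) — stated explicitly because common
clustering tools disagree here. In internal mode (no aligner e-values),
hits are ranked by identity and the e-value cutoff is replaced by
identity ≥ 30%. The permitted start codons default to ATG/GTG/TTG and are
configurable. MSAs are an input (aligned FASTA); no aligner is bundled.
Re-annotated genes always keep their stop codon and a length divisible
by 3, and a second pass over a re-annotated genome changes nothing.

# Per-genome and per-group statistics

`f_overlap_pairs` divides overlapping-pair counts by the total gene count
(so that twice its value approximates the fraction of genes organized in
overlapping pairs — the convention under which a 15% pair fraction
corresponds to 30% of genes); `f_genes_in_overlaps` (distinct genes in
overlapping pairs / genes) is also emitted so both conventions are
available. SD fractions are computed over overlapping-pair downstream
genes and over leading genes; their quotient measures the relative
importance of the SD for reinitiation versus de novo initiation. Undefined
ratios (zero denominators) propagate as missing values, never as zeros,
and are excluded per-metric from group aggregation with the count used
reported. Group dispersion is the sample (n−1) standard deviation.

# Reporter translational efficiencies

Efficiency is activity / transcript per biological replicate, averaged;
the "efficiency" of an empty-vector control is subtracted (so a construct
whose translation is abolished lands near zero, slightly negative values
being legitimate statistical noise and flagged, not clamped); mutants are
normalized to their control, which is exactly 1 by construction. Standard
deviations propagate to first order: the replicate-wise quotient handles
the ratio, subtraction adds variances, and normalization combines relative
errors.

# The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions for every recovery test. A genome is a single plus-strand chain
of ORFs (random non-stop codons, 30–80 codons per gene) whose junctions
are `ATGA` overlaps (default fraction 0.15, the most common overlap type),
`TGATG` overlaps (0.05), or gaps drawn from a geometric distribution with
mean 40 nt plus a point mass (probability 0.5) at ≥ 200 nt that plants
leading genes — with those defaults roughly 40% of genes are leading, the
typical value reported for prokaryotes. Junction constraints are imposed
codon-aware (the penultimate codon before an `ATGA` junction ends in A;
shared bases are written once and verified), so planted overlap histograms
are recovered exactly. One 16S rRNA feature carries an exact anti-SD tail
(`...GATCACCTCCTTA`).

Every gene's 12-nt upstream window is rejection-sampled to a planted SD
class (default mix 0.3/0.4/0.3 none/sd/strong), seeding a
reverse-complement core of the anti-SD (4–6 nt for `sd`, 6–8 nt for
`strong_sd`) and requiring a ±0.5 kcal/mol margin from both thresholds so
that class recovery by the scoring pipeline is exact; the margin is
configurable to stress boundary behavior. Windows that fall inside the
upstream ORF (overlaps and short gaps) respect two constraints: bases of
the upstream stop codon (and the junction-completing A) are immutable, and
rewritten codons of the upstream frame must stay stop-free. When the
immovable bases leave no room for a long core — gaps of roughly 2–6 nt put
the stop codon mid-window — the planted class is downgraded (`strong_sd`
needs a ≥ 7-nt free run, since 6 Watson-Crick stacks reach only about
−8.8 kcal/mol before the margin; `sd` needs ≥ 4) and the truth manifest
records what was actually planted. Overlapping-pair downstream genes and
leading genes are never affected (their windows are unconstrained or
nearly so), so the SD statistics of interest stay clean.

Homolog families plant a true start column shared by a configurable number
of concordant homologs, scatter the rest at mutual distances too large to
form a competing 3-column consensus, displace the query's annotated start
by ±3–9 nt, and reverse-translate the query with an ATG exactly at the
true start and no other in-frame start codon in the contested span — so
recovery is exact and failures are attributable.

Generation is a pure function of (parameters, seed): the caller's RNG
state is saved and restored, and equal seeds produce byte-identical
GenBank output.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: realistic codon usage or GC content,
minus-strand genes and convergent/divergent overlaps, multi-contig
assemblies, rRNA operon multiplicity, sequencing or annotation noise other
than the planted start perturbation, and evolutionary divergence within
homolog families (alignments are gapless apart from leading gaps).

# Problem sizes and determinism

The test suite and the acceptance script use a 2000-gene genome for
fraction/SD recovery, 200 random sequence pairs of length ≤ 6 for the
energy-model cross-check, and 200 homolog families (concordance 7–10,
perturbations ±3–9 nt) for start-recovery; smaller genomes (10–80 genes)
exercise I/O round-trips and invariants. All randomized tests fix their
seeds; the acceptance script derives every seed from its `--seed`
argument.

# Known limitations

* The energy model ignores bulges, internal loops, dangling ends, and
  temperature/salt corrections; it is a ranking device around fixed
  thresholds, not a folding engine, and mRNA secondary structure around
  the start (which can mask an SD) is out of scope.
* Greedy identity clustering is order-dependent by design (length-sorted,
  deterministic) and is a desk-scale stand-in for large-scale clustering
  tools; the selection logic downstream of clustering, not the search
  engine, is the substantive content.
* GenBank parsing covers the common single-interval CDS/rRNA case;
  multi-segment (`join`) features are skipped with a warning rather than
  modeled.
* With a single 16S per genome assumed representative, intra-genomic
  anti-SD heterogeneity is not modeled.
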