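Package: retescan
Title: Overlapping Gene Pairs, Shine-Dalgarno Usage, and the Potential for
    Translational Coupling in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the potential for translational coupling via
    termination-reinitiation in bacterial and archaeal genomes. Enumerates
    co-directional gene pairs and classifies them by signed intergenic
    distance, locates the anti-Shine-Dalgarno tail of the 16S rRNA and scores
    Shine-Dalgarno motifs upstream of translation starts by nearest-neighbor
    RNA:RNA hybridization free energy, re-annotates translation initiation
    sites from homolog alignments by a sliding-window consensus, and
    aggregates per-genome fractions into per-group statistics. Includes a
    synthetic-genome generator with planted ground truth (stop/start codon
    overlaps, gap-length distributions, SD energy classes, perturbed start
    annotations) so the whole pipeline can be exercised and validated without
    external downloads. Reads GenBank flat files or GFF3+FASTA; also provides
    the reporter-gene translational-efficiency arithmetic used to assay
    coupling experimentally.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
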