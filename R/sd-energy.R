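# Shine-Dalgarno detection by RNA:RNA hybridization free energy.
#
# The anti-SD is located as the best match to the canonical ACCUCC in the 3'
# tail of the 16S rRNA, extended by 1 nt on each side to 8 nt. Each gene's
# 12-nt window immediately 5' of the start codon is then hybridized against
# the anti-SD under a nearest-neighbor model restricted to contiguous
# helices (no bulges or internal loops): energy = duplex initiation + sum of
# stacking terms + terminal AU/GU penalties, minimized over every
# registration and every sub-helix. Genes with dG < -3.5 kcal/mol use an SD
# signal; dG < -8.4 kcal/mol is a strong SD.

CANONICAL_ANTI_SD <- "ACCUCC"
SD_THRESHOLD <- -3.5
STRONG_SD_THRESHOLD <- -8.4

#' Load the nearest-neighbor RNA duplex energy model
#'
#' Reads the stacking free energies (kcal/mol at 37 C; Watson-Crick stacks
#' per Xia et al. 1998, GU stacks per the Turner rules) plus the duplex
#' initiation and terminal AU/GU penalties from a versioned parameter file,
#' so alternate parameter sets can be swapped in.
#'
#' @param path parameter TSV (`type`, `key`, `kcal`); defaults to the table
#'   shipped with the package.
#' @param allow_gu permit GU wobble pairs.
#' @return an `EnergyModel`: list with `stack` (named numeric, names like
#'   `"GC/CG"` meaning the step 5'GC3'/3'CG5'), `init`, `terminal_au`,
#'   `terminal_gu`, `allow_gu`, `pairs` (allowed base pairs).
#' @export
energy_model <- function(path = system.file("extdata", "nn_params.tsv",
                                            package = "retescan"),
                         allow_gu = TRUE) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- tab[tab$type == "stack", ]
  model <- structure(list(
    stack = setNames(stacks$kcal, stacks$key),
    init = tab$kcal[tab$type == "init"][1],
    terminal_au = tab$kcal[tab$type == "terminal_au"][1],
    terminal_gu = tab$kcal[tab$type == "terminal_gu"][1],
    allow_gu = allow_gu,
    pairs = if (allow_gu) c("AU", "UA", "CG", "GC", "GU", "UG")
            else c("AU", "UA", "CG", "GC")), class = "EnergyModel")
  step_pairs <- vapply(strsplit(names(model$stack), "/"), function(p)
    paste(paste0(substr(p[1], 1, 1), substr(p[2], 1, 1)),
          paste0(substr(p[1], 2, 2), substr(p[2], 2, 2))), "")
  wc <- !grepl("GU|UG", step_pairs)
  if (any(model$stack[wc] >= 0))
    stop("invalid parameter file: non-negative Watson-Crick stack energy")
  model
}

terminal_penalty <- function(pair, model) {
  ifelse(pair %in% c("AU", "UA"), model$terminal_au,
         ifelse(pair %in% c("GU", "UG"), model$terminal_gu, 0))
}

#' Locate the anti-SD motif in a 16S rRNA 3' tail
#'
#' Scans the tail for the minimum-mismatch match to the canonical anti-SD
#' core ACCUCC (ties broken toward the 3' terminus, where the biological
#' anti-SD sits) and extends the match by 1 nt on each side to 8 nt. If the
#' extension runs past the 5' end of the tail it is padded from `context`
#' (the full 16S sequence) when available; past the 3' terminus of the
#' molecule the motif is clipped with a warning.
#'
#' @param tail RNA (or DNA) string from the 16S 3' end, length >= 8;
#'   default upstream analyses use the final 13 nt.
#' @param context optional full 16S sequence ending in `tail`, used to pad
#'   the 1-nt extension when the best match touches the 5' end of the tail.
#' @return an `AntiSdMotif`: list with `sequence` (8-nt RNA),
#'   `offset_from_3prime` (nt between the motif's 3' end and the tail's 3'
#'   end) and `mismatches_to_canonical`.
#' @export
find_anti_sd <- function(tail, context = NULL) {
  tail <- dna_to_rna(tail)
  n <- nchar(tail)
  if (n < 8L) stop("16S tail must be at least 8 nt, got ", n)
  core <- strsplit(CANONICAL_ANTI_SD, "")[[1]]
  tl <- strsplit(tail, "")[[1]]
  starts <- seq_len(n - 5L)
  mm <- vapply(starts, function(i) sum(tl[i:(i + 5L)] != core), integer(1))
  best <- max(starts[mm == min(mm)])   # ties -> closest to the 3' end
  lo <- best - 1L
  hi <- best + 6L
  seq8 <- tl[max(lo, 1L):min(hi, n)]
  if (lo < 1L) {
    if (!is.null(context)) {
      ctx <- dna_to_rna(context)
      pad <- substr(ctx, nchar(ctx) - n, nchar(ctx) - n)
      if (nzchar(pad)) seq8 <- c(pad, seq8)
    }
    if (length(seq8) < 8L)
      warning("anti-SD extension clipped at the 5' end of the tail")
  }
  if (hi > n)
    warning("anti-SD extension clipped at the 16S 3' terminus")
  structure(list(sequence = paste(seq8, collapse = ""),
                 offset_from_3prime = n - min(hi, n),
                 mismatches_to_canonical = min(mm)),
            class = "AntiSdMotif")
}

#' Extract a genome's anti-SD motif from its 16S rRNA annotation
#'
#' @param genome a [Genome] with at least one 16S rRNA feature.
#' @param tail_length how many 3'-terminal nucleotides of the 16S to scan
#'   (default 13).
#' @return an `AntiSdMotif` (see [find_anti_sd()]).
#' @export
genome_anti_sd <- function(genome, tail_length = 13L) {
  if (nrow(genome$rrnas) == 0L)
    stop("genome '", genome$id, "' has no annotated 16S rRNA")
  rr <- genome$rrnas[1, ]
  full <- dna_to_rna(gene_sequence(genome, rr))
  tail_seq <- substr(full, nchar(full) - tail_length + 1L, nchar(full))
  find_anti_sd(tail_seq, context = full)
}

#' The sequence window immediately upstream of a gene's start codon
#'
#' Returns the `width` nucleotides (default 12) 5' of the start codon on the
#' coding strand, transcribed to RNA; positions -width..-1 only, never
#' spilling into the start codon. Circular contigs wrap across the origin;
#' on linear contigs `NA` is returned when fewer than `width` nt of flank
#' exist.
#'
#' @param genome a [Genome].
#' @param gene one-row CDS record.
#' @param width window width in nt.
#' @return RNA character scalar, or `NA`.
#' @export
upstream_window <- function(genome, gene, width = 12L) {
  if (gene$strand == "+") {
    s <- slice_seq(genome$sequence, gene$start - width, gene$start,
                   genome$topology)
  } else {
    s <- slice_seq(genome$sequence, gene$end, gene$end + width,
                   genome$topology)
    if (!is.na(s)) s <- revcomp_dna(s)
  }
  if (is.na(s)) return(NA_character_)
  dna_to_rna(s)
}

#' Minimum hybridization free energy of two RNA strands
#'
#' Minimizes, over every registration and every contiguous sub-helix, the
#' duplex free energy: initiation + nearest-neighbor stacking terms +
#' terminal AU/GU penalties. No bulges, internal loops or dangling ends.
#' Returns 0 when no duplex has negative energy.
#'
#' The minimization is a dynamic program over pair positions: `chain(i, j)`
#' is the best energy of a stacked run whose 3'-most pair (on the `window`
#' strand) is `window[i] : anti_sd[j]`, either opened at that pair or
#' extended from `chain(i-1, j+1)`.
#'
#' @param window RNA string (the mRNA side), length <= 30.
#' @param anti_sd RNA string (the 16S side, 5'->3'), length <= 13.
#' @param model an [energy_model()].
#' @return free energy in kcal/mol (<= 0).
#' @export
duplex_delta_g <- function(window, anti_sd, model = energy_model()) {
  w <- toupper(window); a <- toupper(anti_sd)
  if (!is_unambiguous_rna(w) || !is_unambiguous_rna(a))
    stop("duplex_delta_g requires unambiguous RNA (A/C/G/U) input")
  if (nchar(w) > 30L || nchar(a) > 13L)
    stop("sequence too long for duplex_delta_g")
  x <- strsplit(w, "")[[1]]; y <- strsplit(a, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0)
  pairs <- outer(x, y, paste0)           # pairs[i, j] = x_i : y_j
  ok <- matrix(pairs %in% model$pairs, n, m)
  pen <- matrix(terminal_penalty(pairs, model), n, m)
  chain <- matrix(Inf, n, m)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!ok[i, j]) next
      e <- pen[i, j]                     # open a helix at (i, j)
      if (i > 1L && j < m && ok[i - 1L, j + 1L]) {
        step <- paste0(x[i - 1L], x[i], "/", y[j + 1L], y[j])
        e <- min(e, chain[i - 1L, j + 1L] + model$stack[[step]])
      }
      chain[i, j] <- e
      best <- min(best, e + pen[i, j] + model$init)
    }
  }
  min(0, best)
}

#' Classify an SD hybridization energy
#'
#' Strict thresholds: `strong_sd` below -8.4 kcal/mol, `sd` below -3.5
#' kcal/mol, otherwise (including exactly -8.4 / -3.5, and undefined
#' energies from absent or ambiguous windows) `none` / `sd`.
#'
#' @param delta_g numeric vector of energies (kcal/mol); `NA` = undefined.
#' @return character vector: `"none"`, `"sd"` or `"strong_sd"`.
#' @export
classify_sd <- function(delta_g) {
  out <- rep("none", length(delta_g))
  out[!is.na(delta_g) & delta_g < SD_THRESHOLD] <- "sd"
  out[!is.na(delta_g) & delta_g < STRONG_SD_THRESHOLD] <- "strong_sd"
  out
}

#' SD calls for every CDS of a genome
#'
#' Extracts each gene's 12-nt upstream window, hybridizes it against the
#' genome's anti-SD motif and classifies the energy. Windows that are absent
#' (insufficient flank on a linear contig) or contain ambiguity codes are
#' called `none` with an undefined energy.
#'
#' @param genome a [Genome].
#' @param anti_sd anti-SD RNA string; defaults to [genome_anti_sd()].
#' @param model an [energy_model()].
#' @param width upstream window width (nt).
#' @return data frame: `gene_id`, `window`, `delta_g`, `sd_class`.
#' @export
sd_calls <- function(genome, anti_sd = NULL, model = energy_model(),
                     width = 12L) {
  if (is.null(anti_sd)) anti_sd <- genome_anti_sd(genome)$sequence
  g <- genome$genes
  windows <- vapply(seq_len(nrow(g)), function(i)
    upstream_window(genome, g[i, ], width), character(1))
  dg <- vapply(windows, function(wd) {
    if (is.na(wd) || !is_unambiguous_rna(wd)) return(NA_real_)
    duplex_delta_g(wd, anti_sd, model)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(gene_id = g$gene_id, window = windows, delta_g = dg,
             sd_class = classify_sd(dg), stringsAsFactors = FALSE)
}
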