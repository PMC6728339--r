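# Independent brute-force oracle for the duplex free energy: enumerate every
# contiguous-helix placement (start position on each strand, helix length)
# and sum stacking terms + initiation + terminal penalties directly. Written
# against the model definition, independently of the dynamic program.
oracle_delta_g <- function(window, anti_sd, model = energy_model()) {
  x <- strsplit(toupper(window), "")[[1]]
  y <- strsplit(toupper(anti_sd), "")[[1]]
  n <- length(x); m <- length(y)
  pen <- function(p) {
    if (p %in% c("AU", "UA")) model$terminal_au
    else if (p %in% c("GU", "UG")) model$terminal_gu
    else 0
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    # helix starting with pair x[i]:y[j], extending x forward / y backward
    kmax <- min(n - i + 1L, j)
    for (k in seq_len(kmax)) {
      pairs <- paste0(x[i:(i + k - 1L)], y[j:(j - k + 1L)])
      if (!all(pairs %in% model$pairs)) break
      e <- model$init + pen(pairs[1]) + pen(pairs[k])
      if (k > 1L) {
        for (t in seq_len(k - 1L)) {
          step <- paste0(x[i + t - 1L], x[i + t], "/",
                         y[j - t + 1L], y[j - t])
          e <- e + model$stack[[step]]
        }
      }
      best <- min(best, e)
    }
  }
  best
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Minimal hand-built genome for classifier tests: `genes` is a data frame
# with gene_id/start/end/strand (kind defaults to CDS).
toy_genome <- function(genes, seq_len = NULL, sequence = NULL,
                       topology = "linear", id = "toy") {
  if (is.null(genes$kind)) genes$kind <- "CDS"
  if (is.null(sequence)) {
    if (is.null(seq_len)) seq_len <- max(genes$end) + 50L
    sequence <- strrep("A", seq_len)
  }
  suppressWarnings(Genome(id, sequence, topology, genes))
}

# Reverse-complement an entire genome (sequence and annotation); distances
# and classifications must be invariant under this flip.
flip_genome <- function(genome) {
  n <- nchar(genome$sequence)
  feats <- rbind(genome$genes, genome$rrnas)
  flipped <- data.frame(
    gene_id = feats$gene_id, kind = feats$kind,
    start = n - feats$end, end = n - feats$start,
    strand = ifelse(feats$strand == "+", "-", "+"),
    product = feats$product, stringsAsFactors = FALSE)
  suppressWarnings(Genome(genome$id,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genome$sequence))),
    genome$topology, flipped))
}
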