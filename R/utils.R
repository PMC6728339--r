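# Small sequence helpers shared across modules. All genome coordinates in this
# package are 0-based half-open on the forward strand; conversion to/from the
# 1-based inclusive convention of GenBank/GFF3 happens at the I/O boundary only.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of a DNA string
#'
#' @param x a character scalar (DNA; IUPAC ambiguity codes allowed).
#' @return the reverse complement as a character scalar.
#' @keywords internal
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_unambiguous_rna <- function(x) {
  !grepl("[^ACGU]", x)
}

#' Extract the coding-strand sequence of a gene
#'
#' Returns `sequence[start:end]`, reverse-complemented for minus-strand genes,
#' so the result always reads 5'->3' in gene orientation.
#'
#' @param genome a [Genome] object.
#' @param gene a single-row gene record (as one row of `genome$genes`).
#' @return DNA character scalar.
#' @export
gene_sequence <- function(genome, gene) {
  s <- substr(genome$sequence, gene$start + 1L, gene$end)
  if (gene$strand == "-") s <- revcomp_dna(s)
  s
}

# Forward-strand slice with circular wrap-around. from/to are 0-based
# half-open; `from` may be negative and `to` may exceed the length when the
# topology is circular.
slice_seq <- function(sequence, from, to, topology = "linear") {
  n <- nchar(sequence)
  if (from >= 0 && to <= n) return(substr(sequence, from + 1L, to))
  if (topology != "circular") return(NA_character_)
  idx <- ((seq.int(from, to - 1L)) %% n) + 1L
  paste(strsplit(sequence, "")[[1]][idx], collapse = "")
}

# Random non-stop codon(s); optionally also excluding start codons.
random_codons <- function(n, exclude = STOP_CODONS) {
  all3 <- expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  pool <- do.call(paste0, all3)
  pool <- setdiff(pool, exclude)
  sample(pool, n, replace = TRUE)
}
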