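#' Genome container
#'
#' An annotated genome: one nucleotide sequence plus its protein-coding genes
#' and 16S rRNA features. Coordinates are 0-based half-open on the forward
#' strand throughout the package; they are converted from the 1-based
#' inclusive convention of GenBank/GFF3 only at the I/O boundary.
#'
#' @param id genome identifier.
#' @param sequence nucleotide sequence (character scalar, uppercased; IUPAC
#'   ambiguity letters are retained).
#' @param topology `"circular"` or `"linear"`.
#' @param genes data frame of gene records with columns `gene_id`, `kind`
#'   (`"CDS"`, `"rRNA_16S"` or `"other"`), `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`), `product`. CDS rows are kept in `$genes` sorted
#'   by start; 16S rRNA rows are kept in `$rrnas`.
#'
#' @return an object of class `Genome`: a list with elements `id`,
#'   `sequence`, `topology`, `genes` (CDS, sorted by `start`) and `rrnas`.
#' @export
Genome <- function(id, sequence, topology = c("linear", "circular"), genes) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- c("gene_id", "kind", "start", "end", "strand")
  if (!all(needed %in% names(genes)))
    stop("gene table must have columns: ", paste(needed, collapse = ", "))
  if (is.null(genes$product)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  n <- nchar(sequence)
  bad <- genes$start < 0L | genes$end > n | genes$start >= genes$end
  if (any(bad))
    stop("invalid coordinates for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  obj <- structure(
    list(id = id,
         sequence = sequence,
         topology = topology,
         genes = genes[genes$kind == "CDS", , drop = FALSE],
         rrnas = genes[genes$kind == "rRNA_16S", , drop = FALSE]),
    class = "Genome")
  if (nrow(obj$genes) == 0L)
    warning("genome '", id, "' contains no CDS features")
  obj
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome '", x$id, "': ", nchar(x$sequence), " nt (", x$topology, "), ",
      nrow(x$genes), " CDS, ", nrow(x$rrnas), " 16S rRNA\n", sep = "")
  invisible(x)
}

#' Look up a gene record by id
#'
#' @param genome a [Genome].
#' @param gene_id gene identifier.
#' @return a one-row data frame.
#' @export
get_gene <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("no such gene: ", gene_id)
  genome$genes[i, , drop = FALSE]
}
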