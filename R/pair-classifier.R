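# Co-directional gene pairs and intergenic-distance classification.
#
# The signed intergenic distance runs from the stop codon of the upstream
# gene to the start codon of the downstream gene: 0 means directly adjacent,
# negative means the codons overlap (ATGA = -4, TGATG = -1).

PAIR_CATEGORIES <- c("overlapping", "adjacent", "close10", "medium50",
                     "far", "lead")

#' Distance-classification configuration
#'
#' @param leading_gene_min_gap minimum intergenic distance (nt) for a gene to
#'   count as "leading", i.e. far enough from its upstream co-directional
#'   gene that reinitiation can be ruled out and initiation must be de novo.
#' @param adjacent_class how to classify distance 0, which the five-class
#'   scheme (negative / 1-9 / 10-50 / >50) leaves unassigned: `"close10"`
#'   folds adjacency into the short-gap class (default; adjacency behaves
#'   like a zero-length gap for reinitiation), `"own_class"` reports it as a
#'   separate `"adjacent"` category.
#' @return a `DistanceConfig` list.
#' @export
distance_config <- function(leading_gene_min_gap = 200L,
                            adjacent_class = c("close10", "own_class")) {
  adjacent_class <- match.arg(adjacent_class)
  leading_gene_min_gap <- as.integer(leading_gene_min_gap)
  if (!leading_gene_min_gap > 50L)
    stop("leading_gene_min_gap must be > 50 nt")
  structure(list(leading_gene_min_gap = leading_gene_min_gap,
                 adjacent_class = adjacent_class),
            class = "DistanceConfig")
}

#' Signed intergenic distance between co-directional genes
#'
#' Plus strand: `downstream$start - upstream$end`; minus strand:
#' `upstream$start - downstream$end`. Zero means directly adjacent stop and
#' start codons; negative values are overlaps.
#'
#' @param upstream,downstream one-row gene records sharing a strand, in
#'   translation order.
#' @return signed integer distance in nt.
#' @export
intergenic_distance <- function(upstream, downstream) {
  if (upstream$strand != downstream$strand)
    stop("genes ", upstream$gene_id, " and ", downstream$gene_id,
         " are on different strands")
  if (upstream$strand == "+") downstream$start - upstream$end
  else upstream$start - downstream$end
}

#' Enumerate co-directional gene pairs
#'
#' Pairs each CDS with the nearest same-strand CDS that follows it in
#' translation order (ascending coordinates on the plus strand, descending
#' on the minus strand); opposite-strand genes in between do not break a
#' pair. Each gene appears as downstream in at most one pair. Pairs do not
#' wrap across the origin of circular contigs.
#'
#' @param genome a [Genome].
#' @return data frame with columns `upstream`, `downstream`, `strand`,
#'   `distance`, `opposite_start_in_gap` and `category` (unset, `NA`).
#' @export
enumerate_codirectional_pairs <- function(genome) {
  g <- genome$genes
  out <- data.frame(upstream = character(), downstream = character(),
                    strand = character(), distance = integer(),
                    opposite_start_in_gap = logical(),
                    category = character(), stringsAsFactors = FALSE)
  for (str in c("+", "-")) {
    gs <- g[g$strand == str, , drop = FALSE]
    if (nrow(gs) < 2L) next
    gs <- gs[order(gs$start, gs$end), , drop = FALSE]
    ord <- if (str == "+") seq_len(nrow(gs)) else rev(seq_len(nrow(gs)))
    opp <- g[g$strand != str, , drop = FALSE]
    # forward-strand coordinate of the first base of an opposite-strand
    # gene's start codon
    opp_start_pos <- if (nrow(opp)) {
      ifelse(opp$strand == "+", opp$start, opp$end - 1L)
    } else integer()
    for (k in seq_len(length(ord) - 1L)) {
      up <- gs[ord[k], ]; dn <- gs[ord[k + 1L], ]
      d <- intergenic_distance(up, dn)
      in_gap <- FALSE
      if (d > 0L) {
        gap_lo <- if (str == "+") up$end else dn$end
        in_gap <- any(opp_start_pos >= gap_lo & opp_start_pos < gap_lo + d)
      }
      out <- rbind(out, data.frame(
        upstream = up$gene_id, downstream = dn$gene_id, strand = str,
        distance = d, opposite_start_in_gap = in_gap,
        category = NA_character_, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify an intergenic distance
#'
#' Five classes: `overlapping` (distance < 0), `close10` (0-9 nt; distance 0
#' configurable, see [distance_config()]), `medium50` (10-50 nt), `far`
#' (> 50 nt, no opposite-strand gene start in the gap) and `lead` (> 50 nt
#' with an opposite-strand gene start in the gap).
#'
#' @param distance signed intergenic distance(s), nt.
#' @param opposite_strand_start_in_gap logical, recycled: does an
#'   opposite-strand CDS start fall strictly inside the intergenic interval?
#' @param config a [distance_config()].
#' @return character vector of categories.
#' @export
classify_pair <- function(distance, opposite_strand_start_in_gap = FALSE,
                          config = distance_config()) {
  n <- length(distance)
  opp <- rep_len(opposite_strand_start_in_gap, n)
  out <- character(n)
  out[distance < 0L] <- "overlapping"
  adj <- if (config$adjacent_class == "close10") "close10" else "adjacent"
  out[distance == 0L] <- adj
  out[distance >= 1L & distance <= 9L] <- "close10"
  out[distance >= 10L & distance <= 50L] <- "medium50"
  out[distance > 50L & !opp] <- "far"
  out[distance > 50L & opp] <- "lead"
  out
}

#' Enumerate and classify all co-directional pairs of a genome
#'
#' @param genome a [Genome].
#' @param config a [distance_config()].
#' @return the pair table of [enumerate_codirectional_pairs()] with
#'   `category` filled in.
#' @export
classify_pairs <- function(genome, config = distance_config()) {
  pairs <- enumerate_codirectional_pairs(genome)
  pairs$category <- classify_pair(pairs$distance,
                                  pairs$opposite_start_in_gap, config)
  pairs
}

#' Identify leading genes
#'
#' A leading gene is separated by at least `leading_gene_min_gap` nt
#' (default 200) from the end of its nearest upstream co-directional gene,
#' or has no upstream co-directional gene on the contig, so that
#' translational coupling can be ruled out and initiation must be de novo.
#'
#' @param genome a [Genome].
#' @param config a [distance_config()].
#' @return character vector of gene ids.
#' @export
identify_leading_genes <- function(genome, config = distance_config()) {
  pairs <- enumerate_codirectional_pairs(genome)
  gap <- setNames(pairs$distance, pairs$downstream)
  ids <- genome$genes$gene_id
  has_up <- ids %in% pairs$downstream
  lead <- !has_up | (has_up & gap[ids] >= config$leading_gene_min_gap)
  ids[which(lead)]
}
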