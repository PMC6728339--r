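# Per-genome fractions and per-group aggregate statistics: fractions of
# overlapping gene pairs, of leading genes, of (strong) SD usage at the
# downstream genes of overlapping pairs vs at leading genes, and the
# quotient of the two SD fractions (the relative importance of the SD motif
# for reinitiation vs de novo initiation).

GENOME_METRICS <- c("f_overlap_pairs", "f_genes_in_overlaps", "f_leading",
                    "f_sd_overlap", "f_strong_sd_overlap", "f_sd_leading",
                    "f_strong_sd_leading", "quotient_sd", "quotient_strong_sd")

#' Summarize one genome
#'
#' Counts and fractions per genome. `f_overlap_pairs` uses the total gene
#' count as denominator (so that twice its value approximates the fraction
#' of genes organized in overlapping pairs); `f_genes_in_overlaps` is the
#' fraction of distinct genes participating in overlapping pairs. SD
#' fractions are computed over the downstream genes of overlapping pairs
#' and over leading genes; quotients are the overlap fraction divided by
#' the leading fraction. Undefined ratios (zero denominators) propagate as
#' `NA`, never as zeros.
#'
#' @param genome a [Genome].
#' @param pairs classified pair table from [classify_pairs()].
#' @param sd_calls SD call table from [sd_calls()]; must cover all
#'   downstream genes of overlapping pairs and all leading genes.
#' @param leading character vector from [identify_leading_genes()].
#' @return a one-row data frame (`GenomeSummary`).
#' @export
summarize_genome <- function(genome, pairs, sd_calls, leading) {
  n_genes <- nrow(genome$genes)
  ov <- pairs[pairs$category == "overlapping", , drop = FALSE]
  required <- unique(c(ov$downstream, leading))
  missing <- setdiff(required, sd_calls$gene_id)
  if (length(missing))
    stop("missing SD call for gene(s): ", paste(missing, collapse = ", "))
  cls <- setNames(sd_calls$sd_class, sd_calls$gene_id)

  n_ov <- nrow(ov)
  n_ov_sd <- sum(cls[ov$downstream] != "none")
  n_ov_strong <- sum(cls[ov$downstream] == "strong_sd")
  n_lead <- length(leading)
  n_lead_sd <- sum(cls[leading] != "none")
  n_lead_strong <- sum(cls[leading] == "strong_sd")

  frac <- function(num, den) if (den > 0L) num / den else NA_real_
  f_sd_overlap <- frac(n_ov_sd, n_ov)
  f_strong_sd_overlap <- frac(n_ov_strong, n_ov)
  f_sd_leading <- frac(n_lead_sd, n_lead)
  f_strong_sd_leading <- frac(n_lead_strong, n_lead)
  quot <- function(num, den)
    if (!is.na(num) && !is.na(den) && den > 0) num / den else NA_real_

  counts <- table(factor(pairs$category, levels = PAIR_CATEGORIES))
  data.frame(
    genome_id = genome$id,
    n_genes = n_genes,
    n_pairs = nrow(pairs),
    n_overlapping = n_ov,
    n_close10 = as.integer(counts[["close10"]]),
    n_medium50 = as.integer(counts[["medium50"]]),
    n_far = as.integer(counts[["far"]]),
    n_lead_class = as.integer(counts[["lead"]]),
    n_overlap_pairs_with_sd = n_ov_sd,
    n_overlap_pairs_with_strong_sd = n_ov_strong,
    n_leading = n_lead,
    n_leading_with_sd = n_lead_sd,
    n_leading_with_strong_sd = n_lead_strong,
    f_overlap_pairs = frac(n_ov, n_genes),
    f_genes_in_overlaps = frac(length(unique(c(ov$upstream, ov$downstream))),
                               n_genes),
    f_leading = frac(n_lead, n_genes),
    f_sd_overlap = f_sd_overlap,
    f_strong_sd_overlap = f_strong_sd_overlap,
    f_sd_leading = f_sd_leading,
    f_strong_sd_leading = f_strong_sd_leading,
    quotient_sd = quot(f_sd_overlap, f_sd_leading),
    quotient_strong_sd = quot(f_strong_sd_overlap, f_strong_sd_leading),
    stringsAsFactors = FALSE)
}

#' Aggregate genome summaries into group statistics
#'
#' Arithmetic mean and sample (n-1) standard deviation of every metric per
#' group; genomes with an undefined (NA) metric are excluded from that
#' metric's aggregation and the count of genomes used is reported.
#'
#' @param summaries data frame of rows from [summarize_genome()].
#' @param group_map data frame with columns `genome_id`, `group` mapping
#'   every genome to exactly one group.
#' @return long-format data frame: `group_id`, `n_genomes`, `metric`,
#'   `mean`, `sd`, `n_used`.
#' @export
aggregate_groups <- function(summaries, group_map) {
  unmapped <- setdiff(summaries$genome_id, group_map$genome_id)
  if (length(unmapped))
    stop("genome(s) not in group map: ", paste(unmapped, collapse = ", "))
  grp <- group_map$group[match(summaries$genome_id, group_map$genome_id)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(summaries)), grp),
    function(idx) {
      rows <- summaries[idx, , drop = FALSE]
      do.call(rbind, lapply(GENOME_METRICS, function(m) {
        v <- rows[[m]]
        v <- v[!is.na(v)]
        data.frame(group_id = grp[idx][1], n_genomes = length(idx),
                   metric = m,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1L) sd(v) else
                        if (length(v) == 1L) 0 else NA_real_,
                   n_used = length(v), stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Read a genome-to-group mapping table
#'
#' @param path 2-column TSV (`genome_id`, `group`), no header required.
#' @return data frame with columns `genome_id`, `group`.
#' @export
read_group_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group map must have 2 columns")
  if (identical(tolower(tab[1, 1]), "genome_id")) tab <- tab[-1, , drop = FALSE]
  setNames(tab[, 1:2], c("genome_id", "group"))
}
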