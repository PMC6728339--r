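# Reporter-gene translational-efficiency arithmetic.
#
# TE = specific enzyme activity / relative transcript level, computed per
# biological replicate and averaged; the "translational efficiency" of an
# empty-vector control is subtracted (the corrected value can therefore be
# slightly negative for untranslated constructs), and mutants are
# normalized to their control construct.

#' Translational efficiency of a reporter construct
#'
#' Computes activity/transcript per replicate, averages across replicates,
#' and subtracts the empty-vector background. Standard deviations are
#' propagated to first order: the replicate-wise TE handles the quotient,
#' and the subtraction adds variances.
#'
#' @param sample data frame of replicates for one construct: columns
#'   `construct_id`, `replicate`, `activity` (nkat/mg), `transcript`
#'   (relative units, 16S-normalized, > 0).
#' @param empty_vector same layout, for the empty-vector negative control.
#' @return a `TranslationalEfficiency` list: `construct_id`, `te_raw`,
#'   `te_raw_sd`, `te_corrected`, `te_corrected_sd`, `n_replicates`.
#' @export
translational_efficiency <- function(sample, empty_vector) {
  raw <- function(df) {
    if (any(df$transcript <= 0))
      stop("zero or negative transcript level for construct ",
           df$construct_id[1])
    df$activity / df$transcript
  }
  te_s <- raw(sample)
  te_e <- raw(empty_vector)
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  structure(list(
    construct_id = sample$construct_id[1],
    te_raw = mean(te_s),
    te_raw_sd = sd0(te_s),
    te_corrected = mean(te_s) - mean(te_e),
    te_corrected_sd = sqrt(sd0(te_s)^2 + sd0(te_e)^2),
    n_replicates = length(te_s)), class = "TranslationalEfficiency")
}

#' Normalize a translational efficiency to a reference construct
#'
#' @param te a `TranslationalEfficiency`.
#' @param reference the control construct's `TranslationalEfficiency`;
#'   its corrected TE must be positive.
#' @return `te` with `te_normalized` and `te_normalized_sd` filled in, and
#'   a `negative` flag for below-background constructs (reported as-is).
#' @export
normalize_to_reference <- function(te, reference) {
  if (!is.finite(reference$te_corrected) || reference$te_corrected <= 0)
    stop("reference construct has non-positive corrected TE")
  ratio <- te$te_corrected / reference$te_corrected
  rel_ref <- reference$te_corrected_sd / reference$te_corrected
  rel_te <- if (te$te_corrected != 0) te$te_corrected_sd / te$te_corrected else 0
  te$te_normalized <- ratio
  te$te_normalized_sd <- if (te$te_corrected != 0)
    abs(ratio) * sqrt(rel_te^2 + rel_ref^2)
  else te$te_corrected_sd / reference$te_corrected
  te$negative <- ratio < 0
  te
}

#' Translational-efficiency table for a measurement set
#'
#' @param measurements data frame with columns `construct_id`, `replicate`,
#'   `activity`, `transcript` covering all constructs including the
#'   empty-vector control and the reference.
#' @param reference construct id to normalize to (its normalized TE is
#'   exactly 1).
#' @param control construct id of the empty-vector negative control.
#' @return data frame: `construct_id`, `te_corrected`, `te_corrected_sd`,
#'   `te_normalized`, `te_normalized_sd`, `negative`.
#' @export
te_table <- function(measurements, reference, control) {
  split_m <- split(measurements, measurements$construct_id)
  if (!control %in% names(split_m)) stop("control construct not found: ", control)
  if (!reference %in% names(split_m)) stop("reference construct not found: ", reference)
  empty <- split_m[[control]]
  tes <- lapply(split_m, translational_efficiency, empty_vector = empty)
  ref <- tes[[reference]]
  rows <- lapply(tes, function(te) {
    te <- normalize_to_reference(te, ref)
    data.frame(construct_id = te$construct_id,
               te_corrected = te$te_corrected,
               te_corrected_sd = te$te_corrected_sd,
               te_normalized = te$te_normalized,
               te_normalized_sd = te$te_normalized_sd,
               negative = te$negative, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a reporter measurement CSV
#'
#' @param path CSV with columns `construct_id`, `replicate`, `activity`,
#'   `transcript`.
#' @return data frame.
#' @export
read_te_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("construct_id", "replicate", "activity", "transcript")
  if (!all(needed %in% names(tab)))
    stop("measurement file must have columns: ", paste(needed, collapse = ", "))
  tab
}
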