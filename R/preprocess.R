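#' Log2-transform raw counts
#'
#' @param values nonnegative numeric vector or matrix (raw scale).
#' @param pseudocount added before taking logs (default 1).
#' @return `log2(values + pseudocount)`, same shape as the input.
#' @export
log2_transform <- function(values, pseudocount = 1.0) {
  if (!is.numeric(values)) abort("'values' must be numeric")
  if (any(values < 0, na.rm = TRUE)) abort("'values' must be nonnegative")
  pseudocount <- check_number(pseudocount, "pseudocount", min = 0)
  log2(values + pseudocount)
}

#' Vehicle-anchored batch correction
#'
#' For every probe and batch, subtracts the mean of that batch's vehicle
#' samples. This removes any per-batch additive shift exactly while leaving
#' all treatment-vs-vehicle contrasts untouched, and it is idempotent: after
#' correction, each batch's vehicle mean is zero for every probe.
#'
#' @param study an [expression_study()]; every batch must contain at least
#'   one vehicle sample.
#' @return The corrected `expression_study`.
#' @export
batch_correct <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  md <- study$metadata
  vals <- study$values
  for (b in unique(md$batch)) {
    in_b <- md$batch == b
    veh <- in_b & md$role == "vehicle"
    if (!any(veh))
      abort(sprintf("batch '%s' has no vehicle sample to anchor on", b))
    anchor <- rowMeans(vals[, veh, drop = FALSE])
    vals[, in_b] <- vals[, in_b, drop = FALSE] - anchor
  }
  expression_study(vals, md)
}

#' Housekeeping geometric-mean normalization of count data
#'
#' Rescales every sample so that all samples share the same housekeeping
#' geometric mean: a sample's scale factor is the global geometric mean of
#' all housekeeping counts divided by that sample's housekeeping geometric
#' mean. Invariant to positive per-sample rescaling and preserves
#' within-sample count ratios.
#'
#' @param counts positive probe x sample count matrix (raw scale).
#' @param housekeeping_ids at least two probe ids present in `counts` whose
#'   counts are strictly positive in every sample.
#' @return The normalized count matrix.
#' @export
normalize_housekeeping <- function(counts, housekeeping_ids) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("'counts' must be a numeric matrix")
  if (length(housekeeping_ids) < 2L)
    abort("need at least 2 housekeeping probes")
  missing_ids <- setdiff(housekeeping_ids, rownames(counts))
  if (length(missing_ids))
    abort("housekeeping probe(s) not in matrix: ",
          paste(missing_ids, collapse = ", "))
  hk <- counts[housekeeping_ids, , drop = FALSE]
  if (any(hk <= 0))
    abort("housekeeping counts must be strictly positive in every sample")
  sample_gm <- exp(colMeans(log(hk)))
  global_gm <- exp(mean(log(hk)))
  factors <- global_gm / sample_gm
  sweep(counts, 2L, factors, "*")
}
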