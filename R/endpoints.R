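as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    abort("'groups' must be a list of at least two numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    abort("every group needs at least two values")
  if (any(!vapply(groups, is.numeric, logical(1))))
    abort("groups must be numeric")
  groups
}

pairwise_table <- function(groups, statistic = c("tukey", "lsd")) {
  statistic <- match.arg(statistic)
  groups <- as_group_list(groups)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  df <- sum(ns) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  pairs <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    diff <- means[i] - means[j]
    if (statistic == "tukey") {
      # Tukey-Kramer studentized range; for equal n this is the classical HSD
      se <- sqrt((mse / 2) * (1 / ns[i] + 1 / ns[j]))
      q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
      p_adj <- if (se > 0) {
        stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      } else if (diff == 0) 1 else 0
      data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
                 difference = diff, q = q, p_adj = p_adj,
                 stringsAsFactors = FALSE)
    } else {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      t <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
      p <- if (se > 0) 2 * stats::pt(-abs(t), df) else if (diff == 0) 1 else 0
      data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
                 difference = diff, t = t, p = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, with studentized-range
#' (Tukey-Kramer) adjusted p-values computed from the pooled mean-square
#' error. When the pooled within-group variance is zero, pairs with equal
#' means get adjusted p = 1 (degenerate) and pairs with different means get
#' adjusted p = 0.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return data.frame with columns `group_a`, `group_b`, `difference`, `q`
#'   (studentized range statistic), `p_adj`.
#' @export
tukey_hsd <- function(groups) pairwise_table(groups, "tukey")

#' Fisher's (unprotected) least significant difference
#'
#' Pairwise t tests using the pooled ANOVA mean-square error and its degrees
#' of freedom, with no multiplicity adjustment.
#'
#' @inheritParams tukey_hsd
#' @return data.frame with columns `group_a`, `group_b`, `difference`, `t`,
#'   `p` (unadjusted).
#' @export
fisher_lsd <- function(groups) pairwise_table(groups, "lsd")

#' Ordinal response call for one endpoint
#'
#' Converts a treated-vs-vehicle comparison into the screen's ordinal call
#' scale. The effect ratio is the absolute treated-vehicle mean difference
#' relative to the calibrating reference effect for the endpoint, and the
#' call is `strong` if p < alpha and ratio >= 0.75, `moderate` if p < alpha
#' and ratio >= 0.25, `inconsistent` if exactly one of the two criteria
#' holds (significant but tiny, or sizeable but not significant), and `none`
#' otherwise. Calls are direction-agnostic.
#'
#' @param treated_values,vehicle_values numeric vectors (>= 3 each).
#' @param reference_effect absolute reference mean difference (> 0) used to
#'   scale the effect; usually the long-acting reference effect, or the
#'   short-acting one for endpoints (TUNEL) where only short-acting
#'   compounds respond.
#' @param alpha significance level.
#' @param method `tukey` or `lsd`; with two groups both reduce to a pooled t
#'   test.
#' @param p optional pre-computed (e.g. multiplicity-adjusted) p-value that
#'   overrides the internal test.
#' @param cutpoints effect-ratio cut points `c(moderate, strong)`.
#' @return List with `call`, `effect_ratio`, `p`, `difference`.
#' @export
call_endpoint <- function(treated_values, vehicle_values, reference_effect,
                          alpha = 0.05, method = c("tukey", "lsd"), p = NULL,
                          cutpoints = c(moderate = 0.25, strong = 0.75)) {
  method <- match.arg(method)
  if (length(treated_values) < 3L || length(vehicle_values) < 3L)
    abort("endpoint calls need at least 3 animals per group")
  if (!is.numeric(reference_effect) || reference_effect <= 0)
    abort("'reference_effect' must be > 0: unusable reference for this endpoint")
  diff <- mean(treated_values) - mean(vehicle_values)
  effect_ratio <- abs(diff) / reference_effect
  if (is.null(p)) {
    tab <- pairwise_table(list(treated = treated_values,
                               vehicle = vehicle_values),
                          if (method == "tukey") "tukey" else "lsd")
    p <- if (method == "tukey") tab$p_adj[1L] else tab$p[1L]
  }
  significant <- p < alpha
  sizeable <- effect_ratio >= cutpoints[["moderate"]]
  call <- if (significant && effect_ratio >= cutpoints[["strong"]]) {
    "strong"
  } else if (significant && sizeable) {
    "moderate"
  } else if (significant || sizeable) {
    "inconsistent"
  } else {
    "none"
  }
  list(call = call, effect_ratio = effect_ratio, p = p, difference = diff)
}
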