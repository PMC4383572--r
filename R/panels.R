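#' Biomarker panel specification
#'
#' @param time_hr timepoint of the panel, 2 or 24.
#' @param contrast_a,contrast_b disjoint nonempty sets of treatment classes
#'   defining the contrast (A vs B); probe directions and the panel axis
#'   point from A towards B.
#' @param k panel size (default 50).
#' @param alpha FDR level for the probe-wise ANOVA filter.
#' @param candidate_patterns archetype labels admitted as candidates; `NULL`
#'   admits every probe (used when patterns are not supplied).
#' @param redundancy_r_max maximum pairwise |r| tolerated within the panel.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(time_hr, contrast_a, contrast_b, k = 50, alpha = 0.05,
                       candidate_patterns = NULL, redundancy_r_max = 0.95) {
  if (!time_hr %in% TIMEPOINTS) abort("'time_hr' must be 2 or 24")
  if (!length(contrast_a) || !length(contrast_b))
    abort("contrast sets must be nonempty")
  if (length(intersect(contrast_a, contrast_b)))
    abort("contrast sets must be disjoint")
  spec <- list(
    time_hr = time_hr,
    contrast_a = as.character(contrast_a),
    contrast_b = as.character(contrast_b),
    k = check_count(k, "k"),
    alpha = check_number(alpha, "alpha"),
    candidate_patterns = candidate_patterns,
    redundancy_r_max = check_number(redundancy_r_max, "redundancy_r_max",
                                    min = 0, max = 1)
  )
  if (spec$alpha <= 0 || spec$alpha >= 1) abort("'alpha' must lie in (0, 1)")
  class(spec) <- "panel_spec"
  spec
}

#' Default 2-h estrogenicity panel specification
#'
#' Contrasts every estrogen class against vehicle at 2 h; candidates come
#' from the archetypes with an early response (transient and sustained).
#' @export
panel_spec_2h <- function() {
  panel_spec(
    time_hr = 2,
    contrast_a = "vehicle",
    contrast_b = c("short_acting", "long_acting", "intermediate"),
    candidate_patterns = c("transient_up", "transient_down",
                           "sustained_up", "sustained_down")
  )
}

#' Default 24-h longevity panel specification
#'
#' Contrasts long- against short-acting references at 24 h; candidates come
#' from the archetypes whose 24-h behaviour separates the two.
#' @export
panel_spec_24h <- function() {
  panel_spec(
    time_hr = 24,
    contrast_a = "short_acting",
    contrast_b = "long_acting",
    candidate_patterns = c("sustained_up", "sustained_down",
                           "late_up_long_only", "late_down_long_only",
                           "long_selective_up")
  )
}

#' Classical one-way ANOVA
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups; total n greater
#'   than the number of groups).
#' @return List with `statistic` (the F ratio), `p_value` (upper tail),
#'   `df_between`, `df_within`, and `degenerate` (`TRUE` when both the
#'   between- and within-group variance are zero, in which case F = 0 and
#'   p = 1).
#' @export
oneway_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) abort("one-way ANOVA needs at least two groups")
  n <- length(values)
  if (length(values) != length(g)) abort("'values' and 'groups' lengths differ")
  k <- nlevels(g)
  if (n <= k) abort("one-way ANOVA needs total n greater than the number of groups")
  counts <- as.integer(table(g))
  means <- as.vector(rowsum(values, g)) / counts
  grand <- mean(values)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((values - means[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0 && ssb == 0)
    return(list(statistic = 0, p_value = 1, df_between = df1, df_within = df2,
                degenerate = TRUE))
  f <- if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2, degenerate = FALSE)
}

# vectorized two-sided one-way F over matrix rows; same conventions as
# oneway_anova
row_oneway <- function(mat, groups) {
  g <- factor(groups)
  n <- ncol(mat)
  k <- nlevels(g)
  counts <- as.integer(table(g))
  gm <- row_group_means(mat, g)
  grand <- rowMeans(mat)
  ssb <- as.vector((gm - grand)^2 %*% counts)
  ssw <- rowSums(mat^2) - as.vector(gm^2 %*% counts)
  ssw <- pmax(ssw, 0)
  f <- ifelse(ssw > 0, (ssb / (k - 1L)) / (ssw / (n - k)),
              ifelse(ssb > 0, Inf, 0))
  p <- ifelse(ssw == 0 & ssb == 0, 1,
              stats::pf(f, k - 1L, n - k, lower.tail = FALSE))
  data.frame(statistic = f, p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted p-values, capped at 1, never smaller than the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    abort("p-values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Principal components of a standardized probe matrix
#'
#' Rows (probes) are standardized to mean 0, SD 1 across samples, then the
#' sample x probe matrix is decomposed by SVD. Loadings are orthonormal
#' per-probe weights, scores are per-sample coordinates, and variance
#' fractions sum to 1. Deterministic sign convention: each component's
#' largest-magnitude loading is positive.
#'
#' @param mat numeric probe x sample matrix with >= 2 rows and columns.
#' @return List with `scores` (samples x components), `loadings`
#'   (probes x components) and `variance_fractions`.
#' @export
principal_components <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L || ncol(mat) < 2L)
    abort("'mat' must be a matrix with at least 2 rows and 2 columns")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0))
    abort("constant row(s) cannot be standardized: ",
          paste(utils::head(rownames(mat)[sds == 0], 5L), collapse = ", "))
  std <- (mat - rowMeans(mat)) / sds
  x <- t(std)  # samples x probes, columns centered by construction
  sv <- svd(x)
  loadings <- sv$v
  scores <- x %*% loadings
  for (j in seq_len(ncol(loadings))) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- rownames(mat)
  rownames(scores) <- colnames(mat)
  list(scores = scores, loadings = loadings,
       variance_fractions = sv$d^2 / sum(sv$d^2))
}

#' Derive a biomarker panel by ANOVA filtering and PCA ranking
#'
#' Procedure, on the study restricted to `spec$time_hr` and the contrast
#' classes: (1) probe-wise one-way ANOVA between the contrast sides with
#' Benjamini-Hochberg control at `spec$alpha`; (2) PCA of the standardized
#' candidate submatrix, selecting the component whose scores correlate most
#' strongly with the contrast indicator; (3) candidates ranked by absolute
#' loading on that component; (4) greedy top-k selection skipping probes
#' correlated above `spec$redundancy_r_max` with an already selected probe.
#' Probe directions are the sign of (mean B - mean A); centroids are the
#' vehicle-relative mean log2 deviations of the panel probes on each side,
#' and the discriminant axis is the unit vector from centroid A to
#' centroid B.
#'
#' @param study a batch-corrected [expression_study()].
#' @param spec a [panel_spec()].
#' @param patterns optional pattern list from [extract_patterns()]; when
#'   supplied, candidates are members of patterns labeled with
#'   `spec$candidate_patterns`, otherwise every probe is a candidate.
#' @return A `biomarker_panel` with `spec`, `probes` (ordered data.frame of
#'   `probe_id`, `direction`, `loading`), `centroid_a`, `centroid_b`, `axis`
#'   and `component`.
#' @export
derive_panel <- function(study, spec, patterns = NULL) {
  stopifnot(inherits(study, "expression_study"), inherits(spec, "panel_spec"))
  md <- study$metadata
  cls <- sample_classes(md)
  keep <- md$time_hr == spec$time_hr &
    cls %in% c(spec$contrast_a, spec$contrast_b)
  if (sum(keep) < 4L)
    abort("empty panel: fewer than 4 contrast samples at ", spec$time_hr, " h")
  side <- ifelse(cls[keep] %in% spec$contrast_b, "B", "A")
  if (length(unique(side)) < 2L)
    abort("empty panel: only one contrast side present at ", spec$time_hr, " h")

  candidates <- if (is.null(patterns)) {
    rownames(study$values)
  } else {
    if (is.null(spec$candidate_patterns))
      abort("spec has no candidate_patterns but patterns were supplied")
    wanted <- vapply(patterns, function(p) p$label %in% spec$candidate_patterns,
                     logical(1))
    unique(unlist(lapply(patterns[wanted], `[[`, "members")))
  }
  if (!length(candidates))
    abort("empty panel: no candidate probes from the admitted patterns")
  candidates <- candidates[radix_order(candidates)]
  sub <- study$values[candidates, keep, drop = FALSE]

  aov_tab <- row_oneway(sub, side)
  padj <- bh_adjust(aov_tab$p_value)
  candidates <- candidates[padj < spec$alpha]
  if (!length(candidates))
    abort("empty panel: the ANOVA/FDR filter removed every candidate")
  sub <- sub[candidates, , drop = FALSE]

  if (length(candidates) == 1L) {
    selected <- candidates
    loadings <- stats::setNames(1, candidates)
    component <- 1L
  } else {
    pca <- principal_components(sub)
    indicator <- as.numeric(side == "B")
    ind_cor <- apply(pca$scores, 2L, function(s) {
      if (stats::sd(s) < 1e-12) 0 else abs(stats::cor(s, indicator))
    })
    component <- which.max(ind_cor)
    load <- pca$loadings[, component]
    ord <- order(-abs(load), candidates, method = "radix")
    rank_ids <- candidates[ord]
    cmat <- stats::cor(t(sub))
    selected <- character(0)
    for (id in rank_ids) {
      if (length(selected) >= spec$k) break
      if (length(selected) &&
          any(abs(cmat[id, selected]) > spec$redundancy_r_max)) next
      selected <- c(selected, id)
    }
    loadings <- load[match(selected, candidates)]
    names(loadings) <- selected
  }

  mean_a <- rowMeans(study$values[selected, keep, drop = FALSE][, side == "A", drop = FALSE])
  mean_b <- rowMeans(study$values[selected, keep, drop = FALSE][, side == "B", drop = FALSE])
  veh <- md$time_hr == spec$time_hr & md$role == "vehicle"
  baseline <- if (any(veh)) {
    rowMeans(study$values[selected, veh, drop = FALSE])
  } else {
    mean_a
  }
  centroid_a <- mean_a - baseline
  centroid_b <- mean_b - baseline
  direction <- ifelse(mean_b - mean_a >= 0, 1L, -1L)
  axis_raw <- centroid_b - centroid_a
  axis_norm <- sqrt(sum(axis_raw^2))
  axis <- if (axis_norm > 0) axis_raw / axis_norm else axis_raw

  structure(list(
    spec = spec,
    probes = data.frame(probe_id = selected, direction = direction,
                        loading = as.numeric(loadings),
                        stringsAsFactors = FALSE),
    centroid_a = centroid_a, centroid_b = centroid_b, axis = axis,
    component = component
  ), class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel (%d h): %d probes, contrast {%s} vs {%s}\n",
              x$spec$time_hr, nrow(x$probes),
              paste(x$spec$contrast_a, collapse = ","),
              paste(x$spec$contrast_b, collapse = ",")))
  invisible(x)
}

#' Validate a panel by hierarchical clustering of samples
#'
#' Samples of the panel's contrast classes (restricted to the panel's
#' timepoint) are clustered by average linkage on correlation distance
#' (1 - r) over the panel probes; the tree is cut into one cluster per
#' contrast side and the clustering is compared to the true side labels by
#' the adjusted Rand index. As in standard expression-heatmap clustering,
#' each probe is centered across the clustered samples first, so arms with
#' no response of their own still cohere through their shared deviation
#' from the panel-wide mean.
#'
#' @param study an [expression_study()].
#' @param panel a `biomarker_panel`.
#' @return Adjusted Rand index in `[-1, 1]` (1 = perfect agreement).
#' @export
validate_panel_clustering <- function(study, panel) {
  stopifnot(inherits(study, "expression_study"),
            inherits(panel, "biomarker_panel"))
  spec <- panel$spec
  md <- study$metadata
  cls <- sample_classes(md)
  keep <- md$time_hr == spec$time_hr &
    cls %in% c(spec$contrast_a, spec$contrast_b)
  side <- ifelse(cls[keep] %in% spec$contrast_b, "B", "A")
  if (length(unique(side)) < 2L)
    abort("panel validation needs both contrast sides")
  if (min(table(side)) < 2L)
    abort("panel validation needs >= 2 samples per contrast side")
  missing_ids <- setdiff(panel$probes$probe_id, rownames(study$values))
  if (length(missing_ids))
    abort("panel probe(s) missing from study: ",
          paste(missing_ids, collapse = ", "))
  sub <- study$values[panel$probes$probe_id, keep, drop = FALSE]
  sub <- sub - rowMeans(sub)
  d <- stats::as.dist(1 - stats::cor(sub))
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      k = length(unique(side)))
  mclust::adjustedRandIndex(cl, side)
}

#' Persist / restore a biomarker panel as JSON
#'
#' @param panel a `biomarker_panel`.
#' @param path JSON file path.
#' @return `write_panel()` returns the panel invisibly; `read_panel()` the
#'   reconstructed panel.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "biomarker_panel"))
  payload <- list(
    spec = unclass(panel$spec),
    probes = panel$probes,
    centroid_a = as.list(panel$centroid_a),
    centroid_b = as.list(panel$centroid_b),
    axis = as.list(panel$axis),
    component = panel$component
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- payload$spec
  spec <- panel_spec(spec$time_hr, spec$contrast_a, spec$contrast_b,
                     k = spec$k, alpha = spec$alpha,
                     candidate_patterns = spec$candidate_patterns,
                     redundancy_r_max = spec$redundancy_r_max)
  structure(list(
    spec = spec,
    probes = payload$probes,
    centroid_a = unlist(payload$centroid_a),
    centroid_b = unlist(payload$centroid_b),
    axis = unlist(payload$axis),
    component = payload$component
  ), class = "biomarker_panel")
}
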