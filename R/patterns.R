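#' Pattern-extraction parameters
#'
#' Thresholds for coexpression-pattern extraction. A probe enters pattern
#' discovery only if its profile's signal-to-noise ratio (range of treatment
#' x time group means over pooled within-group SD) reaches `snr_min` and its
#' largest absolute group-mean log2 deviation from the time-matched vehicle
#' reaches `mag_min` (default 0.585, i.e. 1.5-fold). Patterns are grown from
#' correlation neighborhoods at threshold `r_min` and must reach
#' `min_cluster` members.
#'
#' @param r_min Pearson correlation threshold in (-1, 1).
#' @param snr_min signal-to-noise threshold (>= 0).
#' @param mag_min minimum absolute group-mean log2 deviation from vehicle.
#' @param min_cluster minimum seed-neighborhood size (>= 2).
#' @param snr_cap finite stand-in for an infinite SNR (zero noise).
#' @param label_r_min correlation needed to label a pattern with an archetype.
#' @return A `pattern_params` list.
#' @export
pattern_params <- function(r_min = 0.70, snr_min = 3.0, mag_min = 0.585,
                           min_cluster = 10, snr_cap = 1e6,
                           label_r_min = 0.8) {
  p <- list(
    r_min = check_number(r_min, "r_min"),
    snr_min = check_number(snr_min, "snr_min", min = 0),
    mag_min = check_number(mag_min, "mag_min", min = 0),
    min_cluster = check_count(min_cluster, "min_cluster", min = 2L),
    snr_cap = check_number(snr_cap, "snr_cap", min = 0),
    label_r_min = check_number(label_r_min, "label_r_min", min = -1, max = 1)
  )
  if (p$r_min <= -1 || p$r_min >= 1) abort("'r_min' must lie strictly in (-1, 1)")
  class(p) <- "pattern_params"
  p
}

#' Signal-to-noise ratio of an expression profile
#'
#' SNR = (max group mean - min group mean) / pooled within-group SD. When the
#' pooled SD is zero the SNR is `snr_cap` if the means differ and 0 if every
#' value is identical.
#'
#' @param profile numeric per-sample values.
#' @param group_labels group of each sample (>= 2 groups; at least one group
#'   with >= 2 replicates).
#' @param snr_cap finite stand-in for an infinite SNR.
#' @return Nonnegative scalar.
#' @export
profile_snr <- function(profile, group_labels, snr_cap = 1e6) {
  g <- factor(group_labels)
  if (length(profile) != length(g)) abort("'profile' and 'group_labels' lengths differ")
  if (nlevels(g) < 2L) abort("SNR needs at least two groups")
  if (length(profile) <= nlevels(g))
    abort("SNR needs at least one group with two or more replicates")
  gm <- rowsum(profile, g) / as.integer(table(g))
  rng <- max(gm) - min(gm)
  pooled <- row_pooled_sd(matrix(profile, nrow = 1L), g)
  if (pooled > 0) rng / pooled else if (rng > 0) snr_cap else 0
}

#' Largest absolute group-mean deviation from vehicle
#'
#' @param profile numeric per-sample values.
#' @param group_labels group of each sample.
#' @param vehicle_group label of the vehicle group (must be present).
#' @return Max over non-vehicle groups of |group mean - vehicle mean|, in
#'   log2 units.
#' @export
profile_magnitude <- function(profile, group_labels, vehicle_group) {
  g <- factor(group_labels)
  if (length(profile) != length(g)) abort("'profile' and 'group_labels' lengths differ")
  if (!vehicle_group %in% levels(g))
    abort("vehicle group '", vehicle_group, "' not present")
  gm <- rowsum(profile, g) / as.integer(table(g))
  means <- stats::setNames(as.vector(gm), rownames(gm))
  others <- setdiff(names(means), vehicle_group)
  if (!length(others)) return(0)
  max(abs(means[others] - means[vehicle_group]))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: both vectors must have equal
#' length >= 3 and nonzero variance.
#'
#' @param x,y numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("'x' and 'y' lengths differ")
  if (length(x) < 3L) abort("correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("correlation undefined for a constant vector")
  stats::cor(x, y)
}

# vectorized eligibility statistics used by extract_patterns
probe_filter_stats <- function(study, params) {
  md <- study$metadata
  vals <- study$values
  g <- factor(paste0(md$treatment, "@", md$time_hr))
  if (nlevels(g) < 2L) abort("pattern extraction needs >= 2 treatment x time groups")
  gm <- row_group_means(vals, g)
  pooled <- row_pooled_sd(vals, g)
  rng <- apply(gm, 1L, max) - apply(gm, 1L, min)
  snr <- ifelse(pooled > 0, rng / pooled, ifelse(rng > 0, params$snr_cap, 0))

  mag <- rep(0, nrow(vals))
  for (t in unique(md$time_hr)) {
    veh_g <- paste0("vehicle@", t)
    if (!veh_g %in% colnames(gm))
      abort("no vehicle samples at ", t, " h; magnitude filter needs a vehicle anchor")
    in_t <- grepl(paste0("@", t, "$"), colnames(gm))
    treated <- setdiff(colnames(gm)[in_t], veh_g)
    if (length(treated)) {
      dev <- abs(gm[, treated, drop = FALSE] - gm[, veh_g])
      mag <- pmax(mag, apply(dev, 1L, max))
    }
  }
  data.frame(probe_id = rownames(vals), snr = snr, magnitude = mag,
             sd = apply(vals, 1L, stats::sd), stringsAsFactors = FALSE)
}

#' Extract coexpression patterns
#'
#' Correlation-seeded pattern discovery with signal-to-noise and magnitude
#' prefiltering, on a batch-corrected study:
#'
#' 1. Eligible probes have SNR >= `snr_min` (groups = treatment x time
#'    cells), magnitude >= `mag_min` against the time-matched vehicle, and a
#'    nonconstant profile.
#' 2. Each eligible probe's neighborhood is the set of eligible probes
#'    correlating with it at `r >= r_min`.
#' 3. Iteratively, the unassigned probe with the largest unassigned
#'    neighborhood (ties broken by smallest probe id) seeds a pattern if that
#'    neighborhood reaches `min_cluster`; the neighborhood's mean profile
#'    then absorbs every unassigned eligible probe correlating with it at
#'    `r >= r_min`.
#' 4. After all patterns are formed, each profile is re-fit once as the mean
#'    of its final members.
#'
#' @param study a batch-corrected [expression_study()].
#' @param params a [pattern_params()].
#' @param templates archetype templates for labeling (see
#'   [make_archetype_templates()]), or `NULL` to leave patterns unclassified.
#' @return A list of `coexpression_pattern` objects ordered by creation, each
#'   with `id`, `profile` (per-sample representative values), `members`
#'   (probe ids), `label`, and `stats` (median SNR, median magnitude, size).
#'   Members are disjoint across patterns. No eligible probes yields an
#'   empty list.
#' @export
extract_patterns <- function(study, params = pattern_params(),
                             templates = make_archetype_templates()) {
  stopifnot(inherits(study, "expression_study"))
  stats_tab <- probe_filter_stats(study, params)
  eligible <- stats_tab$snr >= params$snr_min &
    stats_tab$magnitude >= params$mag_min & stats_tab$sd > 0
  if (!any(eligible)) return(list())

  ids <- stats_tab$probe_id[eligible]
  ids <- ids[radix_order(ids)]
  X <- study$values[ids, , drop = FALSE]
  adj <- stats::cor(t(X)) >= params$r_min

  unassigned <- rep(TRUE, length(ids))
  patterns <- list()
  repeat {
    idx_un <- which(unassigned)
    if (!length(idx_un)) break
    counts <- colSums(adj[idx_un, idx_un, drop = FALSE])
    best <- max(counts)
    if (best < params$min_cluster) break
    seed <- idx_un[which(counts == best)[1L]]  # ids are in radix order
    members0 <- idx_un[adj[seed, idx_un]]
    profile0 <- colMeans(X[members0, , drop = FALSE])
    r_prof <- as.vector(stats::cor(t(X[idx_un, , drop = FALSE]), profile0))
    members <- union(members0, idx_un[!is.na(r_prof) & r_prof >= params$r_min])
    members <- sort(members)
    unassigned[members] <- FALSE
    patterns[[length(patterns) + 1L]] <- list(
      id = length(patterns) + 1L,
      members = ids[members],
      initial_profile = profile0
    )
  }

  snr_lookup <- stats::setNames(stats_tab$snr, stats_tab$probe_id)
  mag_lookup <- stats::setNames(stats_tab$magnitude, stats_tab$probe_id)
  lapply(patterns, function(p) {
    p$profile <- colMeans(study$values[p$members, , drop = FALSE])
    p$stats <- list(
      median_snr = stats::median(snr_lookup[p$members]),
      median_magnitude = stats::median(mag_lookup[p$members]),
      size = length(p$members)
    )
    p <- structure(p, class = "coexpression_pattern")
    p$label <- if (is.null(templates)) "unclassified" else
      label_pattern(p, study, templates, min_r = params$label_r_min)
    p
  })
}

#' @export
print.coexpression_pattern <- function(x, ...) {
  cat(sprintf("pattern %d [%s]: %d probes, median SNR %.2f, median |dev| %.2f\n",
              x$id, x$label, x$stats$size, x$stats$median_snr,
              x$stats$median_magnitude))
  invisible(x)
}

#' Assign a profile to the best-matching pattern
#'
#' @param profile per-sample values on the same sample set as the patterns.
#' @param patterns nonempty list from [extract_patterns()].
#' @param r_min minimum correlation to accept an assignment.
#' @return The id of the pattern with maximal correlation if that correlation
#'   reaches `r_min` (ties broken by smallest id), otherwise `NA`.
#' @export
assign_to_patterns <- function(profile, patterns, r_min = 0.70) {
  if (!length(patterns)) abort("'patterns' must be nonempty")
  r <- vapply(patterns, function(p) {
    if (stats::sd(profile) == 0 || stats::sd(p$profile) == 0) return(-Inf)
    stats::cor(profile, p$profile)
  }, numeric(1))
  best <- which.max(r)  # which.max returns the first (smallest-id) maximum
  if (r[best] >= r_min) patterns[[best]]$id else NA_integer_
}

#' Label a pattern with a response archetype
#'
#' Collapses the pattern profile to (treatment class x time) cell means and
#' correlates the cell vector with each archetype template; the best-matching
#' archetype is returned if its correlation reaches `min_r`.
#'
#' @param pattern a `coexpression_pattern`.
#' @param study the study the pattern was extracted from.
#' @param templates archetype list, see [make_archetype_templates()].
#' @param min_r labeling threshold (default 0.8).
#' @return An archetype name, or `"unclassified"`.
#' @export
label_pattern <- function(pattern, study, templates, min_r = 0.8) {
  md <- study$metadata
  cls <- sample_classes(md)
  cell <- paste0(cls, "@", md$time_hr)
  cells <- rowsum(pattern$profile, cell) / as.integer(table(factor(cell)))
  cells <- stats::setNames(as.vector(cells), rownames(cells))
  if (stats::sd(cells) == 0) return("unclassified")
  r <- vapply(templates, function(a) {
    tc <- template_cells(a$template)
    common <- intersect(names(cells), names(tc))
    if (length(common) < 3L || stats::sd(tc[common]) == 0) return(-Inf)
    stats::cor(cells[common], tc[common])
  }, numeric(1))
  best <- which.max(r)
  if (r[best] >= min_r) names(templates)[best] else "unclassified"
}

#' Write a pattern report and per-probe assignments
#'
#' @param patterns list from [extract_patterns()].
#' @param report_path JSON report (id, label, size, stats, members).
#' @param assignments_path optional tab-separated per-probe assignment table.
#' @return Invisibly, the patterns.
#' @export
write_patterns <- function(patterns, report_path, assignments_path = NULL) {
  report <- lapply(patterns, function(p) {
    list(id = p$id, label = p$label, size = p$stats$size,
         median_snr = p$stats$median_snr,
         median_magnitude = p$stats$median_magnitude,
         members = p$members)
  })
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  if (!is.null(assignments_path)) {
    tab <- probe_assignments(patterns)
    utils::write.table(tab, assignments_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(patterns)
}

#' Per-probe pattern membership table
#'
#' @param patterns list from [extract_patterns()].
#' @return data.frame with columns `probe_id`, `pattern_id`, `label`.
#' @export
probe_assignments <- function(patterns) {
  if (!length(patterns))
    return(data.frame(probe_id = character(), pattern_id = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(patterns, function(p) {
    data.frame(probe_id = p$members, pattern_id = p$id, label = p$label,
               stringsAsFactors = FALSE)
  }))
}
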