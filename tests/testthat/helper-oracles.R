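# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive loop-based code paths distinct from the
# package implementation.

# hand-coded Benjamini-Hochberg step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# literal, loop-based re-implementation of the pattern-extraction algorithm
naive_extract_patterns <- function(study, params) {
  md <- study$metadata
  X <- study$values
  groups <- paste0(md$treatment, "@", md$time_hr)
  snr <- mag <- sdv <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    snr[i] <- profile_snr(X[i, ], groups, snr_cap = params$snr_cap)
    per_time <- sapply(unique(md$time_hr), function(t) {
      in_t <- md$time_hr == t
      profile_magnitude(X[i, in_t], paste0(md$treatment[in_t], "@", t),
                        paste0("vehicle@", t))
    })
    mag[i] <- max(per_time)
    sdv[i] <- sd(X[i, ])
  }
  eligible <- which(snr >= params$snr_min & mag >= params$mag_min & sdv > 0)
  if (!length(eligible)) return(list())
  ids <- rownames(X)[eligible]
  ids <- ids[order(ids, method = "radix")]

  nb <- list()
  for (a in ids) {
    nb[[a]] <- ids[vapply(ids, function(b) {
      if (a == b) return(TRUE)
      pearson_r(X[a, ], X[b, ]) >= params$r_min
    }, logical(1))]
  }
  unassigned <- ids
  patterns <- list()
  repeat {
    if (!length(unassigned)) break
    counts <- vapply(unassigned, function(a)
      length(intersect(nb[[a]], unassigned)), integer(1))
    if (max(counts) < params$min_cluster) break
    seed <- unassigned[which(counts == max(counts))[1L]]
    members0 <- intersect(nb[[seed]], unassigned)
    profile0 <- colMeans(X[members0, , drop = FALSE])
    extras <- unassigned[vapply(unassigned, function(a)
      pearson_r(X[a, ], profile0) >= params$r_min, logical(1))]
    members <- union(members0, extras)
    members <- members[order(members, method = "radix")]
    patterns[[length(patterns) + 1L]] <- list(members = members)
    unassigned <- setdiff(unassigned, members)
  }
  for (i in seq_along(patterns))
    patterns[[i]]$profile <- colMeans(X[patterns[[i]]$members, , drop = FALSE])
  patterns
}

# compact reference study for fast tests
small_cfg <- function(seed = 1, ...) {
  sim_config(n_probes = 800, probes_per_archetype = 40, seed = seed, ...)
}

# bespoke single-time study with planted contrast-separating probes; effects
# vary in sign and magnitude (mean |effect| = `effect`) as real regulated
# probe sets do
contrast_study <- function(seed, n_probes = 500, n_planted = 30, reps = 8,
                           effect = 0.5, noise_sd = 0.25) {
  arms <- c("vehicle", "short_acting", "long_acting")
  md <- data.frame(
    sample_id = sprintf("s%03d", seq_len(3 * reps)),
    treatment = rep(arms, each = reps),
    time_hr = 24,
    batch = "batch1",
    role = rep(c("vehicle", "reference", "reference"), each = reps),
    class_label = rep(arms, each = reps),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  X <- matrix(rnorm(n_probes * nrow(md), 0, noise_sd), n_probes, nrow(md),
              dimnames = list(sprintf("probe_%04d", seq_len(n_probes)),
                              md$sample_id))
  sep <- md$class_label == "long_acting"
  eff <- effect * sample(c(-1, 1), n_planted, replace = TRUE) *
    runif(n_planted, 0.7, 1.3)
  X[seq_len(n_planted), sep] <- X[seq_len(n_planted), sep] + eff
  expression_study(X, md)
}

# small fixture family for the brute-force pattern-extraction equivalence:
# <= 12 probes, tiny clusters, varying noise and seeds
brute_force_fixture <- function(seed, noise_sd = 0.2) {
  cfg <- sim_config(n_probes = 12, probes_per_archetype = 1, n_null_probes = 5,
                    noise_sd = noise_sd, n_replicates = 3, batches = 1,
                    batch_shift_sd = 0, seed = seed)
  batch_correct(simulate_reference_study(cfg)$expression)
}

expect_same_patterns <- function(got, want) {
  expect_equal(length(got), length(want))
  for (i in seq_along(got)) {
    expect_identical(sort(got[[i]]$members), sort(want[[i]]$members))
    expect_equal(got[[i]]$profile, want[[i]]$profile, tolerance = 1e-12)
  }
}
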