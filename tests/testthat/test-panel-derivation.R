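test_that("one-way ANOVA matches closed-form and pooled-t oracles", {
  res <- oneway_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 1.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  # identical group means with spread give F = 0
  res0 <- oneway_anova(c(1, 3, 2, 1, 3, 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)

  # degenerate: zero variance everywhere
  resd <- oneway_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(resd$degenerate)
  expect_equal(resd$statistic, 0)
  expect_equal(resd$p_value, 1)

  # two-group F equals the square of the pooled t statistic
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(7); y <- rnorm(5, 0.4)
    res <- oneway_anova(c(x, y), rep(c("a", "b"), c(7, 5)))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand-coded step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, naive_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("principal components match an independent eigendecomposition", {
  set.seed(5)
  m <- matrix(rnorm(48), 8, 6,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:6)))
  pca <- principal_components(m)
  # orthonormal loadings, variance fractions sum to one
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-12)
  expect_true(all(pca$variance_fractions >= 0))
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)

  # oracle: eigendecomposition of the probe correlation matrix
  ev <- eigen(cor(t(m)), symmetric = TRUE)
  std <- (m - rowMeans(m)) / apply(m, 1, sd)
  # eigenvalues of X'X/1 relate to singular values; compare loading spans
  for (j in 1:5) {
    v_pkg <- pca$loadings[, j]
    v_orc <- ev$vectors[, j]
    expect_equal(abs(sum(v_pkg * v_orc)), 1, tolerance = 1e-8)
  }
  expect_equal(pca$variance_fractions[1:5], (ev$values / sum(ev$values))[1:5],
               tolerance = 1e-8)

  # rank-1 data concentrate all variance on the first component
  r1 <- outer(c(1, -2, 0.5, 3), c(1, 2, 3, 4, 5)) + 1:4
  rownames(r1) <- paste0("p", 1:4); colnames(r1) <- paste0("s", 1:5)
  expect_equal(principal_components(r1)$variance_fractions[1], 1,
               tolerance = 1e-12)

  const <- rbind(p1 = rep(1, 4), p2 = rnorm(4))
  expect_error(principal_components(const), "constant row")
})

test_that("panel derivation is deterministic, order-invariant and honors k", {
  st <- contrast_study(seed = 1)
  spec <- panel_spec_24h()
  spec$k <- 10
  a <- derive_panel(st, spec, patterns = NULL)
  b <- derive_panel(st, spec, patterns = NULL)
  expect_identical(a$probes, b$probes)
  expect_lte(nrow(a$probes), 10L)
  expect_equal(sqrt(sum(a$axis^2)), 1, tolerance = 1e-12)
  expect_true(all(a$probes$direction %in% c(-1L, 1L)))

  # permuting probe rows yields the same panel
  perm <- sample(nrow(st$values))
  st_perm <- expression_study(st$values[perm, ], st$metadata)
  c_panel <- derive_panel(st_perm, spec, patterns = NULL)
  expect_identical(c_panel$probes, a$probes)

  # the planted separating probes dominate the selection
  expect_true(all(a$probes$probe_id %in% sprintf("probe_%04d", 1:30)))
})

test_that("panel derivation with k exceeding candidates keeps them all", {
  st <- contrast_study(seed = 3, n_probes = 60, n_planted = 3, effect = 2)
  spec <- panel_spec_24h()
  spec$alpha <- 1e-4
  spec$k <- 3
  pan <- derive_panel(st, spec, patterns = NULL)
  expect_setequal(pan$probes$probe_id, sprintf("probe_%04d", 1:3))
})

test_that("empty-panel errors name the emptying stage", {
  st <- contrast_study(seed = 2, n_planted = 0)
  expect_error(derive_panel(st, panel_spec_24h(), patterns = NULL),
               "ANOVA/FDR")
  # no candidates from patterns
  cfg <- small_cfg(seed = 9)
  ref <- simulate_reference_study(cfg)
  corr <- batch_correct(ref$expression)
  pats <- extract_patterns(corr)
  spec <- panel_spec_24h()
  spec$candidate_patterns <- "no_such_archetype"
  expect_error(derive_panel(corr, spec, pats), "no candidate probes")
})

test_that("panel clustering validation returns calibrated agreement", {
  st <- contrast_study(seed = 5, effect = 1.5)
  spec <- panel_spec_24h(); spec$k <- 20
  pan <- derive_panel(st, spec, patterns = NULL)
  expect_equal(validate_panel_clustering(st, pan), 1)

  # permuted class labels give near-zero agreement on average
  set.seed(77)
  aris <- replicate(100, {
    md <- st$metadata
    treated <- md$class_label != "vehicle"
    md$class_label[treated] <- sample(md$class_label[treated])
    md$treatment <- md$class_label
    validate_panel_clustering(expression_study(st$values, md), pan)
  })
  expect_lt(mean(abs(aris)), 0.1)

  # an unresolvable duplicated sample caps agreement below 1
  md <- st$metadata
  vals <- st$values
  short_idx <- which(md$class_label == "short_acting")[1L]
  long_idx <- which(md$class_label == "long_acting")[1L]
  vals[, long_idx] <- vals[, short_idx]
  expect_lt(validate_panel_clustering(expression_study(vals, md), pan), 1)
})

test_that("panels survive a JSON round trip without drift", {
  st <- contrast_study(seed = 8)
  spec <- panel_spec_24h(); spec$k <- 15
  pan <- derive_panel(st, spec, patterns = NULL)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(pan, path)
  back <- read_panel(path)
  expect_equal(back$probes$probe_id, pan$probes$probe_id)
  expect_equal(back$axis, pan$axis, tolerance = 1e-15)
  expect_equal(back$centroid_a, pan$centroid_a, tolerance = 1e-15)
  # downstream scoring identical
  dev <- compound_deviation(st, pan$probes$probe_id, 24,
                            treatment = "long_acting")
  expect_identical(longevity_score(dev, back), longevity_score(dev, pan))
})
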