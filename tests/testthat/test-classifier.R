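# minimal synthetic panel for score tests; the 2-h panel contrasts against
# vehicle, so its A-side centroid is identically zero
toy_panel <- function(k = 50, seed = 1, time_hr = 24, zero_a = time_hr == 2) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(k))
  ca <- stats::setNames(if (zero_a) rep(0, k) else rnorm(k, 0, 0.1), ids)
  cb <- stats::setNames(rnorm(k, 1, 0.5), ids)
  axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
  structure(list(
    spec = panel_spec(time_hr, "short_acting", "long_acting", k = k),
    probes = data.frame(probe_id = ids, direction = 1L, loading = 1,
                        stringsAsFactors = FALSE),
    centroid_a = ca, centroid_b = cb, axis = axis
  ), class = "biomarker_panel")
}

test_that("the endpoint expectation template encodes the screening scheme", {
  tpl <- class_endpoint_template()
  expect_identical(dim(tpl), c(3L, 9L))
  expect_true(all(tpl["non_estrogenic", ] == "none"))
  expect_identical(unname(tpl["short_acting", ]),
                   c("moderate", "moderate", "wildcard", "wildcard", "wildcard",
                     "moderate", "wildcard", "wildcard", "wildcard"))
  expect_identical(unname(tpl["long_acting", ]),
                   c("moderate", "strong", "moderate", "strong", "strong",
                     "none", "strong", "strong", "strong"))
})

test_that("estrogenicity score is the centroid correlation with exact anchors", {
  pan <- toy_panel(time_hr = 2)
  expect_equal(estrogenicity_score(pan$centroid_b, pan), 1, tolerance = 1e-12)
  expect_equal(estrogenicity_score(-pan$centroid_b, pan), -1, tolerance = 1e-12)
  # missing probes are reported by id
  expect_error(estrogenicity_score(pan$centroid_b[-3], pan), "g003")

  # independent random vectors rarely reach |r| = 0.4
  set.seed(9)
  null_scores <- replicate(400, {
    estrogenicity_score(stats::setNames(rnorm(50), pan$probes$probe_id), pan)
  })
  expect_gt(mean(abs(null_scores) < 0.4), 0.98)
})

test_that("longevity score is affinely calibrated on the reference centroids", {
  pan <- toy_panel()
  expect_equal(longevity_score(pan$centroid_a, pan), 0, tolerance = 1e-12)
  expect_equal(longevity_score(pan$centroid_b, pan), 1, tolerance = 1e-12)
  mid <- (pan$centroid_a + pan$centroid_b) / 2
  expect_equal(longevity_score(mid, pan), 0.5, tolerance = 1e-12)
  # linearity beyond the anchors
  expect_equal(longevity_score(pan$centroid_a + 2 * (pan$centroid_b - pan$centroid_a), pan),
               2, tolerance = 1e-12)
  degen <- pan
  degen$centroid_b <- degen$centroid_a
  expect_error(longevity_score(pan$centroid_a, degen), "degenerate")
})

test_that("classification reproduces the screening-scheme verdicts", {
  all_none <- data.frame(
    endpoint = names(estroscreen:::ENDPOINT_SLOT_MAP),
    call = "none", stringsAsFactors = FALSE
  )
  res <- classify_compound(0.1, 0.02, all_none)
  expect_identical(res$class, "non_estrogenic")

  # calls matching the long-acting row with long-band longevity
  long_calls <- data.frame(
    endpoint = c("edu_pct_24h", "weight_24h", "weight_72h", "tunel_pct_72h",
                 "birc1a_fold_72h", "ltf_fold_72h", "leh_72h"),
    call = c("strong", "moderate", "strong", "none", "strong", "strong",
             "strong"),
    stringsAsFactors = FALSE
  )
  res <- classify_compound(0.9, 0.9, long_calls)
  expect_identical(res$class, "long_acting")
  expect_equal(unname(res$template_distances["long_acting"]), 0)

  # calls matching the short-acting row (wildcards at none), short-band score
  short_calls <- data.frame(
    endpoint = c("edu_pct_24h", "weight_24h", "weight_72h", "tunel_pct_72h",
                 "birc1a_fold_72h", "ltf_fold_72h", "leh_72h"),
    call = c("moderate", "none", "none", "moderate", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
  res <- classify_compound(0.9, 0.1, short_calls)
  expect_identical(res$class, "short_acting")

  # middle band with balanced mismatches: intermediate
  res <- classify_compound(0.9, 0.5, all_none)
  expect_identical(res$class, "intermediate")

  # estrogenic transcripts alone can never yield non-estrogenic
  res <- classify_compound(0.9, NA, all_none[0, ])
  expect_false(res$class == "non_estrogenic")

  # quiet transcripts with an inconsistent call fall through to templates
  one_off <- all_none
  one_off$call[3] <- "inconsistent"
  res <- classify_compound(0.05, 0.0, one_off)
  expect_false(res$class == "non_estrogenic")
})

test_that("classification is invariant to probe order and extra probes", {
  cfg <- small_cfg(seed = 13)
  ref <- simulate_reference_study(cfg)
  corr <- batch_correct(ref$expression)
  pats <- extract_patterns(corr)
  pan2 <- derive_panel(corr, panel_spec_2h(), pats)
  pan24 <- derive_panel(corr, panel_spec_24h(), pats)

  tc <- simulate_test_compound("long_acting", seed = 3, cfg = cfg)
  cc <- batch_correct(tc$expression)
  dev2 <- compound_deviation(cc, pan2$probes$probe_id, 2)
  dev24 <- compound_deviation(cc, pan24$probes$probe_id, 24)
  e0 <- estrogenicity_score(dev2, pan2)
  l0 <- longevity_score(dev24, pan24)

  # shuffled and padded deviation vectors give identical scores
  set.seed(1)
  extra <- stats::setNames(rnorm(20), sprintf("junk%02d", 1:20))
  dev2_b <- sample(c(dev2, extra))
  dev24_b <- sample(c(dev24, extra))
  expect_identical(estrogenicity_score(dev2_b, pan2), e0)
  expect_identical(longevity_score(dev24_b, pan24), l0)
})
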