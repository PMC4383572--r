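test_that("archetype templates satisfy their structural invariants", {
  tpl <- make_archetype_templates()
  expect_length(tpl, 7L)
  expect_named(tpl, ARCHETYPE_NAMES)
  for (a in tpl) {
    tm <- a$template
    expect_identical(dim(tm), c(4L, 2L))
    expect_true(all(tm["vehicle", ] == 0))
    expect_equal(tm["intermediate", ],
                 (tm["short_acting", ] + tm["long_acting", ]) / 2)
  }
  # transient: nonzero at 2 h for every estrogen class, zero at 24 h
  for (nm in c("transient_up", "transient_down")) {
    tm <- tpl[[nm]]$template
    expect_true(all(abs(tm[c("short_acting", "long_acting", "intermediate"), "2"]) > 0))
    expect_true(all(tm[, "24"] == 0))
  }
  # long-only: silent at 2 h, nonzero at 24 h for long-acting, zero for short
  for (nm in c("late_up_long_only", "late_down_long_only")) {
    tm <- tpl[[nm]]$template
    expect_true(all(tm[, "2"] == 0))
    expect_true(abs(tm["long_acting", "24"]) > 0)
    expect_identical(tm["short_acting", "24"], 0)
  }
  # sustained: both times for long-acting; early only for short-acting
  for (nm in c("sustained_up", "sustained_down")) {
    tm <- tpl[[nm]]$template
    expect_true(all(abs(tm["long_acting", ]) > 0))
    expect_true(abs(tm["short_acting", "2"]) > 0)
    expect_identical(tm["short_acting", "24"], 0)
  }
  # mutual separability under the default correlation threshold: no pair of
  # collapsed templates (sign included) correlates above r_min
  cells <- sapply(tpl, function(a) as.vector(a$template[-1, ]))
  cc <- cor(cells)
  diag(cc) <- 0
  expect_lt(max(cc), pattern_params()$r_min)
})

test_that("reference simulation is deterministic and honors its config", {
  cfg <- small_cfg(seed = 7)
  a <- simulate_reference_study(cfg)
  b <- simulate_reference_study(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(nrow(a$expression$values), cfg$n_probes)
  md <- a$expression$metadata
  expect_setequal(unique(md$treatment), TREATMENT_CLASSES)
  expect_equal(nrow(md), 4 * 2 * cfg$n_replicates)
  # every batch holds vehicle samples (round-robin assignment)
  expect_true(all(table(md$batch[md$role == "vehicle"]) >= 1))
  # truth covers every probe
  expect_identical(names(a$truth$probe_archetype), rownames(a$expression$values))
})

test_that("zero-noise studies reproduce template means exactly", {
  cfg <- small_cfg(seed = 3, noise_sd = 0, batch_shift_sd = 0)
  st <- simulate_reference_study(cfg)
  md <- st$expression$metadata
  vals <- st$expression$values
  # replicates identical within every treatment x time cell
  cell <- paste(md$treatment, md$time_hr)
  for (cl in unique(cell)) {
    sub <- vals[, cell == cl, drop = FALSE]
    expect_true(all(sub == sub[, 1L]))
  }
  # vehicle-relative group means equal template x effect exactly
  tpl <- make_archetype_templates()
  truth <- st$truth$probe_archetype
  for (nm in c("transient_up", "sustained_down", "long_selective_up")) {
    probe <- names(truth)[which(truth == nm)[1L]]
    for (tr in c("short_acting", "long_acting", "intermediate")) {
      for (t in c(2, 24)) {
        dev <- mean(vals[probe, md$treatment == tr & md$time_hr == t]) -
          mean(vals[probe, md$treatment == "vehicle" & md$time_hr == t])
        expect_equal(dev, tpl[[nm]]$template[tr, as.character(t)] * cfg$effect_size,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("noisy group means recover the generative means within Monte-Carlo error", {
  cfg <- sim_config(n_probes = 2000, probes_per_archetype = 100, seed = 1)
  st <- simulate_reference_study(cfg)
  md <- st$expression$metadata
  truth <- st$truth$probe_archetype
  tpl <- make_archetype_templates()
  probes <- names(truth)[truth %in% "transient_up" & !is.na(truth)]
  long2 <- md$treatment == "long_acting" & md$time_hr == 2
  veh2 <- md$treatment == "vehicle" & md$time_hr == 2
  dev <- rowMeans(st$expression$values[probes, long2]) -
    rowMeans(st$expression$values[probes, veh2])
  expected <- tpl$transient_up$template["long_acting", "2"] * cfg$effect_size
  se <- cfg$noise_sd * sqrt(1 / sum(long2) + 1 / sum(veh2)) / sqrt(length(probes))
  expect_lt(abs(mean(dev) - expected), 3 * se)
})

test_that("test-compound simulation respects class, potency and persistence", {
  cfg <- small_cfg(seed = 5, noise_sd = 0, batch_shift_sd = 0)
  tpl <- make_archetype_templates()

  dev_of <- function(study, probe, tr, t) {
    md <- study$expression$metadata
    v <- study$expression$values
    mean(v[probe, md$treatment == tr & md$time_hr == t]) -
      mean(v[probe, md$treatment == "vehicle" & md$time_hr == t])
  }

  null_c <- simulate_test_compound("non_estrogenic", seed = 2, cfg = cfg)
  truth <- null_c$truth$probe_archetype
  probe_s <- names(truth)[which(truth == "sustained_up")[1L]]
  expect_equal(dev_of(null_c, probe_s, "test", 2), 0, tolerance = 1e-12)
  expect_equal(dev_of(null_c, probe_s, "test", 24), 0, tolerance = 1e-12)

  long_c <- simulate_test_compound("long_acting", seed = 2, cfg = cfg)
  expect_equal(dev_of(long_c, probe_s, "test", 24),
               tpl$sustained_up$template["long_acting", "24"], tolerance = 1e-12)

  # persistence scales the 24-h component to zero, potency scales everything
  fade <- simulate_test_compound("long_acting", potency = 2, persistence = 0,
                                 seed = 2, cfg = cfg)
  expect_equal(dev_of(fade, probe_s, "test", 24), 0, tolerance = 1e-12)
  expect_equal(dev_of(fade, probe_s, "test", 2),
               2 * tpl$sustained_up$template["long_acting", "2"], tolerance = 1e-12)

  expect_error(simulate_test_compound("estrogen_x", cfg = cfg), "class_label")
  expect_error(simulate_test_compound("long_acting", potency = -1, cfg = cfg),
               "potency")
})

test_that("phenotype simulation is deterministic with class-driven means", {
  a <- simulate_phenotypes("short_acting", seed = 11)
  b <- simulate_phenotypes("short_acting", seed = 11)
  expect_identical(a, b)
  expect_error(simulate_phenotypes("short_acting", n_animals = 2), "at least three")

  # short-acting compounds show more 72-h apoptosis than long-acting
  eff <- phenotype_effect_config()
  shrt <- simulate_phenotypes("short_acting", n_animals = 20, seed = 4)
  lng <- simulate_phenotypes("long_acting", n_animals = 20, seed = 4)
  tunel <- function(tab, tr) mean(tab$value[tab$endpoint == "tunel_pct_72h" &
                                              tab$treatment == tr])
  expect_lt(tunel(lng, "long_acting"), tunel(shrt, "short_acting"))

  # null class sits at vehicle level in expectation
  null_tab <- simulate_phenotypes("non_estrogenic", n_animals = 60, seed = 9)
  for (ep in eff$endpoint[!grepl("_pct_", eff$endpoint)]) {
    m_t <- mean(null_tab$value[null_tab$endpoint == ep &
                                 null_tab$treatment == "non_estrogenic"])
    m_v <- mean(null_tab$value[null_tab$endpoint == ep &
                                 null_tab$treatment == "vehicle"])
    sd_e <- eff$sd[eff$endpoint == ep]
    expect_lt(abs(m_t - m_v), 4 * sd_e * sqrt(2 / 60))
  }
})
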