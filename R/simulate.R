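#' Simulation configuration
#'
#' Defaults mirror the scale of a multi-study uterine microarray compendium:
#' 10,000 probes of which 7 x 300 follow the response archetypes, unit log2
#' effect size, replicate noise SD 0.25, four replicates per treatment x time
#' cell split round-robin over two batches with per-probe batch shifts
#' (SD 0.3). Per-probe baseline intensities are drawn from N(8, 1) on the
#' log2 scale.
#'
#' @param n_probes total number of probes.
#' @param probes_per_archetype planted probes per archetype (7 archetypes).
#' @param n_null_probes noise-only probes; defaults to the remainder.
#' @param effect_size log2 units multiplying every archetype template.
#' @param noise_sd replicate noise SD (log2 units).
#' @param n_replicates replicates per treatment x time cell.
#' @param batches number of batches (samples assigned round-robin).
#' @param batch_shift_sd SD of the additive per-probe, per-batch shift.
#' @param baseline_mean,baseline_sd per-probe baseline intensity distribution.
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 10000, probes_per_archetype = 300,
                       n_null_probes = NULL, effect_size = 1.0,
                       noise_sd = 0.25, n_replicates = 4, batches = 2,
                       batch_shift_sd = 0.3, baseline_mean = 8,
                       baseline_sd = 1, seed = 1) {
  cfg <- list(
    n_probes = check_count(n_probes, "n_probes"),
    probes_per_archetype = check_count(probes_per_archetype, "probes_per_archetype"),
    effect_size = check_number(effect_size, "effect_size"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    n_replicates = check_count(n_replicates, "n_replicates"),
    batches = check_count(batches, "batches"),
    batch_shift_sd = check_number(batch_shift_sd, "batch_shift_sd", min = 0),
    baseline_mean = check_number(baseline_mean, "baseline_mean"),
    baseline_sd = check_number(baseline_sd, "baseline_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  n_arch <- length(ARCHETYPE_NAMES)
  planted <- cfg$probes_per_archetype * n_arch
  cfg$n_null_probes <- if (is.null(n_null_probes)) {
    cfg$n_probes - planted
  } else {
    check_count(n_null_probes, "n_null_probes", min = 0L)
  }
  if (planted + cfg$n_null_probes > cfg$n_probes)
    abort("'n_probes' must be >= probes_per_archetype * 7 + n_null_probes")
  if (cfg$n_replicates < cfg$batches)
    abort("'n_replicates' must be >= 'batches' so every batch gets vehicle samples")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic probe labels and archetype assignment
probe_assignment <- function(cfg) {
  ids <- sprintf("probe_%05d", seq_len(cfg$n_probes))
  archetype <- rep(NA_character_, cfg$n_probes)
  planted <- rep(ARCHETYPE_NAMES, each = cfg$probes_per_archetype)
  archetype[seq_along(planted)] <- planted
  names(archetype) <- ids
  archetype
}

# one arm = one treatment label with a class determining its template column
# and optional potency/persistence multipliers
build_design <- function(arms, cfg) {
  rows <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    expand.grid(rep = seq_len(cfg$n_replicates), time_hr = TIMEPOINTS,
                arm = i, KEEP.OUT.ATTRS = FALSE)
  }))
  md <- data.frame(
    sample_id = sprintf("s%03d_%s_%dh_r%d", seq_len(nrow(rows)),
                        arms$treatment[rows$arm], rows$time_hr, rows$rep),
    treatment = arms$treatment[rows$arm],
    time_hr = rows$time_hr,
    batch = paste0("batch", ((seq_len(nrow(rows)) - 1L) %% cfg$batches) + 1L),
    role = arms$role[rows$arm],
    class_label = arms$class_label[rows$arm],
    stringsAsFactors = FALSE
  )
  md
}

# expected (noise-free, vehicle-relative) mean for each archetype in one
# treatment x time cell
archetype_cell_means <- function(templates, class_label, time_hr, effect,
                                 potency = 1, persistence = 1) {
  vapply(templates, function(a) {
    if (!class_label %in% rownames(a$template)) return(0)
    v <- a$template[class_label, as.character(time_hr)] * effect * potency
    if (time_hr == 24) v <- v * persistence
    v
  }, numeric(1))
}

simulate_study_core <- function(cfg, arms, seed) {
  templates <- make_archetype_templates()
  archetype <- probe_assignment(cfg)
  md <- build_design(arms, cfg)
  n_s <- nrow(md)

  mu <- matrix(0, nrow = cfg$n_probes, ncol = n_s,
               dimnames = list(names(archetype), md$sample_id))
  planted <- which(!is.na(archetype))
  arch_idx <- match(archetype[planted], ARCHETYPE_NAMES)
  for (j in seq_len(n_s)) {
    i <- match(md$treatment[j], arms$treatment)
    cell <- archetype_cell_means(
      templates, arms$class_label[i], md$time_hr[j], cfg$effect_size,
      potency = arms$potency[i], persistence = arms$persistence[i]
    )
    mu[planted, j] <- cell[arch_idx]
  }

  withr::with_seed(seed, {
    baseline <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
    shifts <- matrix(stats::rnorm(cfg$n_probes * cfg$batches, 0, cfg$batch_shift_sd),
                     nrow = cfg$n_probes)
    noise <- matrix(stats::rnorm(cfg$n_probes * n_s, 0, cfg$noise_sd),
                    nrow = cfg$n_probes)
  })
  batch_idx <- as.integer(sub("^batch", "", md$batch))
  values <- mu + baseline + shifts[, batch_idx, drop = FALSE] + noise
  dimnames(values) <- dimnames(mu)
  list(expression = expression_study(values, md), probe_archetype = archetype)
}

#' Simulate a reference study
#'
#' Generates the screen's training material: a vehicle arm plus proven
#' short-acting, long-acting and intermediate reference estrogens at 2 h and
#' 24 h, with planted archetype probes, batch structure and replicate noise,
#' together with a reference phenotype table and the generating truth.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_study` list with elements `expression`
#'   (an [expression_study()]), `phenotypes` (animal-level endpoint table),
#'   and `truth` (per-probe archetype and per-treatment class labels).
#' @export
simulate_reference_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  arms <- data.frame(
    treatment = c("vehicle", "short_acting", "long_acting", "intermediate"),
    class_label = c("vehicle", "short_acting", "long_acting", "intermediate"),
    role = c("vehicle", "reference", "reference", "reference"),
    potency = 1, persistence = 1, stringsAsFactors = FALSE
  )
  core <- simulate_study_core(cfg, arms, seed = cfg$seed)
  phen <- simulate_phenotypes(
    c("short_acting", "long_acting", "intermediate"),
    seed = cfg$seed + 1L
  )
  truth <- list(
    probe_archetype = core$probe_archetype,
    compound_class = stats::setNames(
      arms$class_label[arms$role != "vehicle"],
      arms$treatment[arms$role != "vehicle"]
    )
  )
  structure(list(expression = core$expression, phenotypes = phen,
                 truth = truth), class = "synthetic_study")
}

#' Simulate a test compound study
#'
#' The compound's expression response is the archetype template column for
#' its class scaled by `potency`, with all 24-h components additionally
#' scaled by `persistence`; a `non_estrogenic` compound has zero template
#' everywhere. Phenotypes are generated from the class's endpoint means.
#'
#' @param class_label one of `non_estrogenic`, `short_acting`, `long_acting`,
#'   `intermediate`.
#' @param potency nonnegative multiplier on the expression template.
#' @param persistence fraction in `[0, 1]` scaling 24-h expression responses.
#' @param seed integer seed.
#' @param cfg a [sim_config()]; the probe space matches
#'   [simulate_reference_study()] under the same `cfg`.
#' @param name treatment label for the compound arm.
#' @details The phenotype experiment carries a concurrent long-acting
#'   reference arm (`reference_long`) alongside vehicle and the compound,
#'   mirroring the in-vivo design in which every candidate-compound bioassay
#'   includes a proven estrogen; endpoint tests can then pool variance and
#'   adjust across all arms. Internally the compound generator salts the
#'   seed with a fixed offset so that compound draws never alias the
#'   reference study's random stream when the two are built from the same
#'   seed; the output remains a pure function of `(inputs, seed)`.
#' @return A `synthetic_study`; see [simulate_reference_study()].
#' @export
simulate_test_compound <- function(class_label, potency = 1, persistence = 1,
                                   seed = 1, cfg = sim_config(), name = "test") {
  classes <- c("non_estrogenic", "short_acting", "long_acting", "intermediate")
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% classes)
    abort("unknown class_label; expected one of: ", paste(classes, collapse = ", "))
  potency <- check_number(potency, "potency", min = 0)
  persistence <- check_number(persistence, "persistence", min = 0, max = 1)
  seed <- check_count(seed, "seed", min = 0L)
  stopifnot(inherits(cfg, "sim_config"))
  arms <- data.frame(
    treatment = c("vehicle", name),
    class_label = c("vehicle", class_label),
    role = c("vehicle", "test"),
    potency = c(1, potency), persistence = c(1, persistence),
    stringsAsFactors = FALSE
  )
  seed_core <- bitwXor(seed, 1431655765L)  # decouple from reference streams
  core <- simulate_study_core(cfg, arms, seed = seed_core)
  phen <- simulate_phenotypes(c(class_label, "long_acting"),
                              seed = seed_core + 1L,
                              treatments = c(name, "reference_long"))
  truth <- list(
    probe_archetype = core$probe_archetype,
    compound_class = stats::setNames(c(class_label, "long_acting"),
                                     c(name, "reference_long"))
  )
  structure(list(expression = core$expression, phenotypes = phen,
                 truth = truth), class = "synthetic_study")
}

#' Endpoint means used by the phenotype generator
#'
#' Group means for the seven phenotypic endpoints of the screen, per
#' treatment class, with animal-to-animal Gaussian noise SD and the class
#' whose response calibrates the endpoint (`responder`). Long-acting
#' estrogens drive large 72-h weight, epithelial height and Birc1a/Ltf
#' responses with near-vehicle TUNEL; short-acting estrogens drive the 24-h
#' EdU response, an attenuated 72-h growth response, and elevated TUNEL.
#' Intermediates sit at the midpoint of the two; non-estrogenic compounds at
#' vehicle level. Units: mg (weight), % (EdU, TUNEL), micrometers (epithelial
#' cell height), fold induction (Birc1a, Ltf).
#'
#' @return data.frame with columns `endpoint`, `vehicle`, `short_acting`,
#'   `long_acting`, `sd`, `responder`.
#' @export
phenotype_effect_config <- function() {
  data.frame(
    endpoint = c("weight_24h", "weight_72h", "edu_pct_24h", "tunel_pct_72h",
                 "leh_72h", "birc1a_fold_72h", "ltf_fold_72h"),
    vehicle      = c(25,  30,  5,  1,   10, 1,   1),
    short_acting = c(32,  45, 60, 12,   18, 1.5, 2),
    long_acting  = c(50, 120, 70,  1.5, 30, 8,  50),
    sd           = c(4,    8,  6,  1.5,  2, 0.8, 5),
    responder = c("long_acting", "long_acting", "long_acting", "short_acting",
                  "long_acting", "long_acting", "long_acting"),
    stringsAsFactors = FALSE
  )
}

class_endpoint_mean <- function(cfg_row, class_label) {
  switch(class_label,
    vehicle = ,
    non_estrogenic = cfg_row$vehicle,
    short_acting = cfg_row$short_acting,
    long_acting = cfg_row$long_acting,
    intermediate = (cfg_row$short_acting + cfg_row$long_acting) / 2,
    abort("unknown class_label: ", class_label)
  )
}

#' Simulate animal-level phenotype endpoints
#'
#' Generates a shared vehicle arm plus one arm per requested class, with
#' group means from [phenotype_effect_config()] and i.i.d. Gaussian
#' animal-to-animal noise. Percentage endpoints are truncated to `[0, 100]`.
#'
#' @param class_label character vector of treatment classes (one arm each).
#' @param n_animals animals per group (>= 3; downstream statistics require at
#'   least three per group).
#' @param effect_cfg endpoint mean table, see [phenotype_effect_config()].
#' @param seed integer seed.
#' @param treatments treatment labels for the arms (defaults to the classes).
#' @return Long-format data.frame with columns `animal_id`, `treatment`,
#'   `endpoint`, `value`.
#' @export
simulate_phenotypes <- function(class_label, n_animals = 5,
                                effect_cfg = phenotype_effect_config(),
                                seed = 1, treatments = class_label) {
  classes <- c("non_estrogenic", "short_acting", "long_acting", "intermediate")
  if (!length(class_label) || !all(class_label %in% classes))
    abort("class_label entries must be one of: ", paste(classes, collapse = ", "))
  if (length(treatments) != length(class_label) || anyDuplicated(treatments))
    abort("'treatments' must be unique labels, one per class_label")
  n_animals <- check_count(n_animals, "n_animals")
  if (n_animals < 3)
    abort("'n_animals' must be >= 3: group statistics need at least three animals per group")
  seed <- check_count(seed, "seed", min = 0L)

  groups <- data.frame(treatment = c("vehicle", treatments),
                       class_label = c("vehicle", class_label),
                       stringsAsFactors = FALSE)
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
      do.call(rbind, lapply(seq_len(nrow(effect_cfg)), function(e) {
        m <- class_endpoint_mean(effect_cfg[e, ], groups$class_label[g])
        val <- stats::rnorm(n_animals, m, effect_cfg$sd[e])
        if (grepl("_pct_", effect_cfg$endpoint[e]))
          val <- pmin(pmax(val, 0), 100)
        data.frame(
          animal_id = sprintf("%s_a%02d", groups$treatment[g], seq_len(n_animals)),
          treatment = groups$treatment[g],
          endpoint = effect_cfg$endpoint[e],
          value = val, stringsAsFactors = FALSE
        )
      }))
    }))
  })
  rownames(rows) <- NULL
  validate_phenotypes(rows)
  rows
}
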