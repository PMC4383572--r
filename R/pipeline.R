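#' Full-screen run configuration
#'
#' Bundles every stage's parameters behind one object with a single global
#' seed. The seed fans out by fixed offsets (reference expression: `seed`;
#' reference phenotypes: `seed + 1`; compound i: `seed + 100 + i` for its
#' expression and that value + 1 for its phenotypes), so stages are
#' independently re-runnable and a fixed seed makes the whole run
#' bit-reproducible.
#'
#' @param sim [sim_config()] for the synthetic reference and compounds.
#' @param pattern_params [pattern_params()].
#' @param spec_2h,spec_24h [panel_spec()]s for the two panels.
#' @param thresholds [classifier_thresholds()].
#' @param phenotype_cfg [phenotype_effect_config()] table.
#' @param n_animals animals per phenotype group.
#' @param endpoint_method `tukey` or `lsd` for endpoint p-values.
#' @param endpoint_alpha significance level for endpoint calls.
#' @param compounds data.frame with columns `name`, `class_label` and
#'   optionally `potency`, `persistence`, `seed`, `with_2h`, `with_24h`,
#'   `with_phenotypes`.
#' @param seed global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), pattern_params = NULL,
                       spec_2h = panel_spec_2h(), spec_24h = panel_spec_24h(),
                       thresholds = classifier_thresholds(),
                       phenotype_cfg = phenotype_effect_config(),
                       n_animals = 5, endpoint_method = c("tukey", "lsd"),
                       endpoint_alpha = 0.05,
                       compounds = default_compounds(), seed = 1) {
  seed <- check_count(seed, "seed", min = 0L)
  sim$seed <- seed
  if (is.null(pattern_params)) pattern_params <- estroscreen::pattern_params()
  structure(list(
    sim = sim, pattern_params = pattern_params,
    spec_2h = spec_2h, spec_24h = spec_24h, thresholds = thresholds,
    phenotype_cfg = phenotype_cfg,
    n_animals = check_count(n_animals, "n_animals", min = 3L),
    endpoint_method = match.arg(endpoint_method),
    endpoint_alpha = check_number(endpoint_alpha, "endpoint_alpha"),
    compounds = compounds, seed = seed
  ), class = "run_config")
}

#' Example test-compound panel: one compound per class
#' @export
default_compounds <- function() {
  data.frame(
    name = c("cmpd_null", "cmpd_short", "cmpd_long", "cmpd_mid"),
    class_label = c("non_estrogenic", "short_acting", "long_acting",
                    "intermediate"),
    potency = 1, persistence = 1, stringsAsFactors = FALSE
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort(stage, ": ", conditionMessage(e)))
}

#' Measured reference effects per phenotype endpoint
#'
#' For every endpoint, the absolute difference between the calibrating
#' responder class's group mean and the vehicle mean, measured from a
#' reference phenotype table. These effects scale the effect ratios of
#' endpoint calls.
#'
#' @param phenotypes long-format phenotype table containing vehicle and the
#'   responder classes.
#' @param effect_cfg endpoint table naming each endpoint's responder class,
#'   see [phenotype_effect_config()].
#' @return Named numeric vector of reference effects.
#' @export
reference_effects <- function(phenotypes, effect_cfg = phenotype_effect_config()) {
  vapply(seq_len(nrow(effect_cfg)), function(i) {
    ep <- effect_cfg$endpoint[i]
    responder <- effect_cfg$responder[i]
    sub <- phenotypes[phenotypes$endpoint == ep, ]
    if (!responder %in% sub$treatment || !"vehicle" %in% sub$treatment)
      abort("reference table lacks vehicle or ", responder, " for ", ep)
    abs(mean(sub$value[sub$treatment == responder]) -
          mean(sub$value[sub$treatment == "vehicle"]))
  }, numeric(1)) |> stats::setNames(effect_cfg$endpoint)
}

#' Ordinal calls for every endpoint of a compound's phenotype table
#'
#' For each endpoint, a one-way ANOVA across every arm in the table yields
#' the treated-vs-vehicle p-value (Tukey studentized-range adjusted, or
#' Fisher LSD), the way concurrent reference arms are handled in the
#' uterotrophic bioassay; the family of endpoint p-values is then
#' Benjamini-Hochberg adjusted, and each endpoint is converted to an
#' ordinal call with [call_endpoint()].
#'
#' @param phenotypes long-format table with a vehicle arm, the treated arm,
#'   and optionally further arms (e.g. a concurrent long-acting reference)
#'   that enter the pooled ANOVA.
#' @param ref_effects named reference effects from [reference_effects()].
#' @param treatment treated arm label; defaults to the single non-vehicle
#'   treatment.
#' @param alpha significance level.
#' @param method `tukey` or `lsd`.
#' @param adjust BH-adjust the endpoint family (default TRUE).
#' @param cutpoints effect-ratio cut points.
#' @return data.frame with columns `endpoint`, `call`, `effect_ratio`, `p`.
#' @export
endpoint_response_calls <- function(phenotypes, ref_effects, treatment = NULL,
                                    alpha = 0.05, method = c("tukey", "lsd"),
                                    adjust = TRUE,
                                    cutpoints = c(moderate = 0.25,
                                                  strong = 0.75)) {
  method <- match.arg(method)
  arms <- unique(phenotypes$treatment)
  if (!"vehicle" %in% arms) abort("phenotype table has no vehicle arm")
  if (is.null(treatment)) {
    treated_arms <- setdiff(arms, c("vehicle", "reference_long"))
    if (length(treated_arms) != 1L)
      abort("phenotype table has ", length(treated_arms),
            " candidate treated arms; name one via 'treatment'")
    treatment <- treated_arms
  }
  if (!treatment %in% arms) abort("no arm named '", treatment, "'")
  endpoints <- intersect(names(ref_effects), unique(phenotypes$endpoint))
  if (!length(endpoints)) abort("no endpoints shared with the reference effects")
  groups <- lapply(endpoints, function(ep) {
    sub <- phenotypes[phenotypes$endpoint == ep, ]
    g <- split(sub$value, sub$treatment)
    g[c(treatment, "vehicle", setdiff(names(g), c(treatment, "vehicle")))]
  })
  p_raw <- vapply(groups, function(g) {
    tab <- pairwise_table(g, if (method == "tukey") "tukey" else "lsd")
    row <- (tab$group_a == treatment & tab$group_b == "vehicle") |
      (tab$group_b == treatment & tab$group_a == "vehicle")
    if (method == "tukey") tab$p_adj[row] else tab$p[row]
  }, numeric(1))
  p_use <- if (adjust) bh_adjust(p_raw) else p_raw
  out <- lapply(seq_along(endpoints), function(i) {
    res <- call_endpoint(groups[[i]][[treatment]], groups[[i]][["vehicle"]],
                         ref_effects[[endpoints[i]]], alpha = alpha,
                         method = method, p = p_use[i], cutpoints = cutpoints)
    data.frame(endpoint = endpoints[i], call = res$call,
               effect_ratio = res$effect_ratio, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the reference side of the screen
#'
#' Simulates (or loads) the reference study, batch-corrects it, extracts and
#' labels coexpression patterns, derives the 2-h and 24-h biomarker panels,
#' validates both by clustering, and measures the reference phenotype
#' effects. When `out_dir` is given, every artifact is written there
#' (tab-separated tables and JSON reports) together with a parameter log.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return List with the corrected reference study, patterns, both panels,
#'   their adjusted Rand indices, the reference phenotypes and effects.
#' @export
run_reference_build <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ref <- with_stage("simulate", simulate_reference_study(config$sim))
  corrected <- with_stage("batch_correct", batch_correct(ref$expression))
  patterns <- with_stage("extract_patterns",
                         extract_patterns(corrected, config$pattern_params))
  panel_2h <- with_stage("derive_panel_2h",
                         derive_panel(corrected, config$spec_2h, patterns))
  panel_24h <- with_stage("derive_panel_24h",
                          derive_panel(corrected, config$spec_24h, patterns))
  ari_2h <- with_stage("validate_panel_2h",
                       validate_panel_clustering(corrected, panel_2h))
  ari_24h <- with_stage("validate_panel_24h",
                        validate_panel_clustering(corrected, panel_24h))
  ref_effects <- with_stage("reference_effects",
                            reference_effects(ref$phenotypes, config$phenotype_cfg))
  result <- list(reference = ref, corrected = corrected, patterns = patterns,
                 panel_2h = panel_2h, panel_24h = panel_24h,
                 ari_2h = ari_2h, ari_24h = ari_24h,
                 ref_effects = ref_effects)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_study(corrected, file.path(out_dir, "reference_expression.tsv"),
                file.path(out_dir, "reference_metadata.tsv"))
    write_patterns(patterns, file.path(out_dir, "patterns.json"),
                   file.path(out_dir, "pattern_assignments.tsv"))
    write_panel(panel_2h, file.path(out_dir, "panel_2h.json"))
    write_panel(panel_24h, file.path(out_dir, "panel_24h.json"))
    write_phenotypes(ref$phenotypes, file.path(out_dir, "reference_phenotypes.tsv"))
    effects_tab <- data.frame(endpoint = names(ref_effects),
                              reference_effect = format_full(ref_effects))
    utils::write.table(effects_tab, file.path(out_dir, "reference_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(
      sprintf("stage=reference_build seed=%d n_probes=%d probes_per_archetype=%d",
              config$seed, config$sim$n_probes, config$sim$probes_per_archetype),
      sprintf("patterns=%d panel_2h=%d panel_24h=%d ari_2h=%.4f ari_24h=%.4f",
              length(patterns), nrow(panel_2h$probes), nrow(panel_24h$probes),
              ari_2h, ari_24h)
    )
    writeLines(log_lines, file.path(out_dir, "reference_build.log"))
  }
  result
}

#' Screen test compounds against built panels
#'
#' For every compound row in the configuration: simulate its study, compute
#' vehicle-relative deviations for the available timepoints, score both
#' panels, call phenotype endpoints (BH-adjusted family), and classify.
#' A compound with no usable modality produces a per-compound error entry
#' and the run continues.
#'
#' @param config a [run_config()].
#' @param reference result of [run_reference_build()].
#' @param out_dir optional output directory for the classification report.
#' @return Named list, one `compound_classification` (or error entry) per
#'   compound.
#' @export
run_compound_screen <- function(config, reference, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cmp <- config$compounds
  get_col <- function(col, default) {
    if (col %in% names(cmp)) cmp[[col]] else rep(default, nrow(cmp))
  }
  potency <- get_col("potency", 1)
  persistence <- get_col("persistence", 1)
  seeds <- get_col("seed", NA_real_)
  with_2h <- get_col("with_2h", TRUE)
  with_24h <- get_col("with_24h", TRUE)
  with_phen <- get_col("with_phenotypes", TRUE)

  results <- lapply(seq_len(nrow(cmp)), function(i) {
    tryCatch({
      if (!with_2h[i] && !with_24h[i] && !with_phen[i])
        abort("no usable modality for compound ", cmp$name[i])
      seed_i <- if (is.na(seeds[i])) config$seed + 100L + i else as.integer(seeds[i])
      study <- simulate_test_compound(cmp$class_label[i], potency[i],
                                      persistence[i], seed = seed_i,
                                      cfg = config$sim, name = cmp$name[i])
      corrected <- batch_correct(study$expression)
      e_score <- if (with_2h[i]) {
        dev2 <- compound_deviation(corrected,
                                   reference$panel_2h$probes$probe_id, 2)
        estrogenicity_score(dev2, reference$panel_2h)
      } else NA_real_
      l_score <- if (with_24h[i]) {
        dev24 <- compound_deviation(corrected,
                                    reference$panel_24h$probes$probe_id, 24)
        longevity_score(dev24, reference$panel_24h)
      } else NA_real_
      calls <- if (with_phen[i]) {
        endpoint_response_calls(study$phenotypes, reference$ref_effects,
                                treatment = cmp$name[i],
                                alpha = config$endpoint_alpha,
                                method = config$endpoint_method,
                                cutpoints = config$thresholds$call_cutpoints)
      } else {
        data.frame(endpoint = character(), call = character(),
                   stringsAsFactors = FALSE)
      }
      cls <- classify_compound(e_score, l_score, calls,
                               thresholds = config$thresholds)
      cls$compound <- cmp$name[i]
      cls
    }, error = function(e) {
      list(compound = cmp$name[i], error = conditionMessage(e))
    })
  })
  names(results) <- cmp$name
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_classifications(results, file.path(out_dir, "classifications.json"))
  }
  results
}

#' Persist classification results as JSON
#'
#' @param results list from [run_compound_screen()].
#' @param path JSON file path.
#' @export
write_classifications <- function(results, path) {
  payload <- lapply(results, function(r) {
    if (!is.null(r$error)) return(list(compound = r$compound, error = r$error))
    list(compound = r$compound, class = r$class,
         estrogenicity_2h = r$estrogenicity_2h,
         longevity_24h = r$longevity_24h,
         endpoint_calls = r$endpoint_calls,
         template_distances = as.list(r$template_distances),
         evidence = r$evidence)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(results)
}

#' Run the whole screen
#'
#' Reference build followed by the compound screen, with all artifacts
#' written under `out_dir`. A fixed seed yields byte-identical outputs
#' across reruns.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return List with `reference` (see [run_reference_build()]) and
#'   `classifications` (see [run_compound_screen()]).
#' @export
run_all <- function(config, out_dir) {
  reference <- run_reference_build(config, out_dir = out_dir)
  classifications <- run_compound_screen(config, reference, out_dir = out_dir)
  invisible(list(reference = reference, classifications = classifications))
}
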