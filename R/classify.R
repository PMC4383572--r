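#' @name classification
#' @title Rule-based compound classification
#'
#' @description
#' The final verdict combines two transcriptional scores (estrogenicity at
#' 2 h, longevity at 24 h) with ordinal phenotype calls matched against a
#' per-class endpoint template: non-estrogenic compounds show no response
#' anywhere; short-acting estrogens share the early transcriptional and
#' proliferative response but fail to sustain 24-72-h growth and show
#' elevated apoptosis (TUNEL); long-acting estrogens sustain everything with
#' near-vehicle TUNEL; compounds between the two templates are called
#' intermediate.
NULL

ENDPOINT_SLOTS <- c("2h_rna_panel", "24h_edu", "24h_weight", "72h_weight",
                  "24h_rna_panel", "72h_tunel", "72h_birc1a", "72h_ltf",
                  "72h_leh")

ENDPOINT_SLOT_MAP <- c(
  edu_pct_24h = "24h_edu", weight_24h = "24h_weight",
  weight_72h = "72h_weight", tunel_pct_72h = "72h_tunel",
  birc1a_fold_72h = "72h_birc1a", ltf_fold_72h = "72h_ltf",
  leh_72h = "72h_leh"
)

#' Per-class endpoint expectation template
#'
#' Expected ordinal calls per compound class and endpoint slot. `wildcard`
#' encodes "some or inconsistent response" and matches `none`,
#' `inconsistent` or `moderate`; `moderate` matches at least a moderate
#' response (`moderate` or `strong`); `strong` and `none` match only
#' themselves.
#'
#' @return character matrix, classes x endpoint slots.
#' @export
class_endpoint_template <- function() {
  tpl <- rbind(
    non_estrogenic = rep("none", 9L),
    short_acting = c("moderate", "moderate", "wildcard", "wildcard",
                     "wildcard", "moderate", "wildcard", "wildcard",
                     "wildcard"),
    long_acting = c("moderate", "strong", "moderate", "strong", "strong",
                    "none", "strong", "strong", "strong")
  )
  colnames(tpl) <- ENDPOINT_SLOTS
  tpl
}

call_matches <- function(observed, expected) {
  switch(expected,
    none = observed == "none",
    wildcard = observed %in% c("none", "inconsistent", "moderate"),
    moderate = observed %in% c("moderate", "strong"),
    strong = observed == "strong",
    abort("unknown expected call: ", expected)
  )
}

#' Convert a panel score into an ordinal call
#'
#' @param score panel score (estrogenicity or longevity).
#' @param cutpoints `c(moderate, strong)` cut points.
#' @return `"strong"`, `"moderate"` or `"none"`.
#' @export
score_to_call <- function(score, cutpoints = c(moderate = 0.25, strong = 0.75)) {
  if (is.na(score)) return(NA_character_)
  if (score >= cutpoints[["strong"]]) "strong"
  else if (score >= cutpoints[["moderate"]]) "moderate"
  else "none"
}

#' Classifier decision thresholds
#'
#' @param tau_e estrogenicity threshold below which (with all-null endpoint
#'   calls) a compound is non-estrogenic.
#' @param longevity_short,longevity_long longevity-score band edges: scores
#'   below `longevity_short` are short-acting territory, above
#'   `longevity_long` long-acting, and the middle band is the explicit
#'   intermediate zone.
#' @param call_cutpoints effect-ratio / score cut points for ordinal calls.
#' @return A `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(tau_e = 0.5, longevity_short = 0.35,
                                  longevity_long = 0.65,
                                  call_cutpoints = c(moderate = 0.25,
                                                     strong = 0.75)) {
  structure(list(
    tau_e = check_number(tau_e, "tau_e", min = -1, max = 1),
    longevity_short = check_number(longevity_short, "longevity_short"),
    longevity_long = check_number(longevity_long, "longevity_long"),
    call_cutpoints = call_cutpoints
  ), class = "classifier_thresholds")
}

check_panel_coverage <- function(deviation, panel) {
  ids <- panel$probes$probe_id
  missing_ids <- setdiff(ids, names(deviation))
  if (length(missing_ids))
    abort("panel probe(s) missing from the test deviations: ",
          paste(missing_ids, collapse = ", "))
  deviation[ids]
}

#' Estrogenicity score against the 2-h panel
#'
#' Pearson correlation between the compound's per-probe mean log2 deviation
#' from vehicle at 2 h and the panel's estrogen-reference centroid contrast
#' (centroid B - centroid A).
#'
#' @param test_deviation_2h named numeric vector of per-probe deviations
#'   covering the panel probes.
#' @param panel_2h the 2-h `biomarker_panel`.
#' @return Score in `[-1, 1]`.
#' @export
estrogenicity_score <- function(test_deviation_2h, panel_2h) {
  dev <- check_panel_coverage(test_deviation_2h, panel_2h)
  ref <- panel_2h$centroid_b - panel_2h$centroid_a
  if (stats::sd(ref) == 0) abort("degenerate panel: constant reference centroid")
  pearson_r(dev, ref)
}

#' Longevity score against the 24-h panel
#'
#' Projects the compound's 24-h deviation vector onto the panel's
#' discriminant axis, affinely calibrated so the short-acting reference
#' centroid maps to 0 and the long-acting centroid to 1.
#'
#' @param test_deviation_24h named numeric vector of per-probe deviations
#'   covering the panel probes.
#' @param panel_24h the 24-h `biomarker_panel`.
#' @return Calibrated scalar (0 = short-acting references, 1 = long-acting).
#' @export
longevity_score <- function(test_deviation_24h, panel_24h) {
  dev <- check_panel_coverage(test_deviation_24h, panel_24h)
  span <- sum((panel_24h$centroid_b - panel_24h$centroid_a) * panel_24h$axis)
  if (!is.finite(span) || abs(span) < 1e-12)
    abort("degenerate panel axis: contrast centroids coincide")
  sum((dev - panel_24h$centroid_a) * panel_24h$axis) / span
}

#' Mean vehicle-relative deviation of a compound over selected probes
#'
#' @param study an [expression_study()] containing the compound (`role ==
#'   "test"`, or a named treatment) and vehicle samples.
#' @param probe_ids probes to extract (error lists any missing ids).
#' @param time_hr 2 or 24.
#' @param treatment optional treatment label; defaults to all `test` samples.
#' @return Named numeric vector of per-probe mean log2 deviations from the
#'   time-matched vehicle.
#' @export
compound_deviation <- function(study, probe_ids, time_hr, treatment = NULL) {
  stopifnot(inherits(study, "expression_study"))
  md <- study$metadata
  missing_ids <- setdiff(probe_ids, rownames(study$values))
  if (length(missing_ids))
    abort("probe(s) missing from study: ", paste(missing_ids, collapse = ", "))
  test <- md$time_hr == time_hr &
    (if (is.null(treatment)) md$role == "test" else md$treatment == treatment)
  veh <- md$time_hr == time_hr & md$role == "vehicle"
  if (!any(test)) abort("no test samples at ", time_hr, " h")
  if (!any(veh)) abort("no vehicle samples at ", time_hr, " h")
  rowMeans(study$values[probe_ids, test, drop = FALSE]) -
    rowMeans(study$values[probe_ids, veh, drop = FALSE])
}

#' Classify a compound from transcriptional scores and endpoint calls
#'
#' Decision rule: (1) a compound with estrogenicity below `tau_e` and every
#' available phenotype call equal to `none` is non-estrogenic; (2) otherwise
#' the observed calls (including calls derived from the two panel scores)
#' are matched against the short- and long-acting template rows, counting
#' mismatches with wildcards free; (3) a longevity score in the long band
#' with no more long- than short-row mismatches gives `long_acting`, the
#' mirror case `short_acting`; (4) anything else - the middle band, or a
#' score/template disagreement - is `intermediate`. Unavailable evidence
#' reduces the mismatch counts, never errors.
#'
#' @param estrogenicity 2-h panel score (`NA` if unavailable).
#' @param longevity 24-h panel score (`NA` if unavailable).
#' @param endpoint_calls data.frame with columns `endpoint` (phenotype
#'   endpoint or slot name) and `call`; may be empty.
#' @param template expectation matrix, see [class_endpoint_template()].
#' @param thresholds a [classifier_thresholds()].
#' @return A `compound_classification` with `class`, the two scores, the
#'   observed slot calls, per-class `template_distances`, and a free-text
#'   `evidence` trail.
#' @export
classify_compound <- function(estrogenicity, longevity, endpoint_calls,
                              template = class_endpoint_template(),
                              thresholds = classifier_thresholds()) {
  estrogenicity <- if (is.null(estrogenicity)) NA_real_ else as.numeric(estrogenicity)
  longevity <- if (is.null(longevity)) NA_real_ else as.numeric(longevity)
  observed <- stats::setNames(rep(NA_character_, length(ENDPOINT_SLOTS)),
                              ENDPOINT_SLOTS)
  observed["2h_rna_panel"] <- score_to_call(estrogenicity,
                                            thresholds$call_cutpoints)
  observed["24h_rna_panel"] <- score_to_call(longevity,
                                             thresholds$call_cutpoints)
  pheno_calls <- character(0)
  if (!is.null(endpoint_calls) && nrow(endpoint_calls)) {
    slots <- ifelse(endpoint_calls$endpoint %in% names(ENDPOINT_SLOT_MAP),
                    ENDPOINT_SLOT_MAP[endpoint_calls$endpoint],
                    endpoint_calls$endpoint)
    unknown <- setdiff(slots, ENDPOINT_SLOTS)
    if (length(unknown))
      abort("unknown endpoint(s): ", paste(unknown, collapse = ", "))
    observed[slots] <- endpoint_calls$call
    pheno_calls <- endpoint_calls$call
  }

  evidence <- character(0)
  add_ev <- function(...) evidence <<- c(evidence, sprintf(...))
  add_ev("estrogenicity_2h = %s",
         if (is.na(estrogenicity)) "unavailable" else sprintf("%.3f", estrogenicity))
  add_ev("longevity_24h = %s",
         if (is.na(longevity)) "undetermined" else sprintf("%.3f", longevity))

  mismatches <- vapply(c("short_acting", "long_acting"), function(cl) {
    avail <- !is.na(observed)
    sum(!mapply(call_matches, observed[avail], template[cl, avail]))
  }, numeric(1))

  has_evidence <- !is.na(estrogenicity) || length(pheno_calls) > 0
  quiet_transcripts <- is.na(estrogenicity) || estrogenicity < thresholds$tau_e
  all_null_calls <- length(pheno_calls) == 0 || all(pheno_calls == "none")

  cls <- if (has_evidence && quiet_transcripts && all_null_calls) {
    add_ev("no transcriptional or phenotypic estrogen response")
    "non_estrogenic"
  } else if (is.na(longevity)) {
    add_ev("longevity undetermined; deciding on template mismatches alone (short %d vs long %d)",
           mismatches[["short_acting"]], mismatches[["long_acting"]])
    if (mismatches[["short_acting"]] < mismatches[["long_acting"]]) "short_acting"
    else if (mismatches[["long_acting"]] < mismatches[["short_acting"]]) "long_acting"
    else "intermediate"
  } else if (longevity > thresholds$longevity_long &&
             mismatches[["long_acting"]] <= mismatches[["short_acting"]]) {
    add_ev("longevity in long band; template mismatches short %d vs long %d",
           mismatches[["short_acting"]], mismatches[["long_acting"]])
    "long_acting"
  } else if (longevity < thresholds$longevity_short &&
             mismatches[["short_acting"]] <= mismatches[["long_acting"]]) {
    add_ev("longevity in short band; template mismatches short %d vs long %d",
           mismatches[["short_acting"]], mismatches[["long_acting"]])
    "short_acting"
  } else {
    add_ev("middle longevity band or score/template disagreement (short %d vs long %d)",
           mismatches[["short_acting"]], mismatches[["long_acting"]])
    "intermediate"
  }

  structure(list(
    class = cls,
    estrogenicity_2h = estrogenicity,
    longevity_24h = longevity,
    endpoint_calls = data.frame(slot = ENDPOINT_SLOTS, call = unname(observed),
                                stringsAsFactors = FALSE),
    template_distances = mismatches,
    evidence = evidence
  ), class = "compound_classification")
}

#' @export
print.compound_classification <- function(x, ...) {
  cat(sprintf("compound_classification: %s\n", x$class))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}
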