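#' @name archetypes
#' @title Uterine estrogen-response archetypes
#'
#' @description
#' Seven archetypal transcript response shapes over the design
#' (treatment class x time) used both to plant signal in synthetic studies
#' and to label extracted coexpression patterns:
#'
#' * `transient_up` / `transient_down`: regulated at 2 h by every estrogen
#'   class, back to vehicle level by 24 h.
#' * `sustained_up` / `sustained_down`: regulated at 2 h by every estrogen
#'   class; only long-acting estrogens maintain (and deepen) the response
#'   at 24 h, short-acting estrogens return to baseline.
#' * `late_up_long_only` / `late_down_long_only`: silent at 2 h, regulated at
#'   24 h by long-acting estrogens only.
#' * `long_selective_up`: induced at both times, but only by long-acting
#'   estrogens.
#'
#' Template cells are unitless log2 deviations from vehicle for a unit effect
#' size; the intermediate class is always the arithmetic midpoint of the
#' short- and long-acting cells, matching a partial-agonist phenotype.
#' Within each archetype the relative cell amplitudes are fixed so that every
#' pairwise correlation between collapsed templates stays at or below 0.49,
#' well under the default pattern-correlation threshold (0.70) -- otherwise
#' distinct planted archetypes would be statistically inseparable by
#' correlation-seeded clustering; see the methods vignette.
NULL

#' Treatment classes recognized by the screen
#' @export
TREATMENT_CLASSES <- c("vehicle", "short_acting", "long_acting", "intermediate")

#' Archetype names
#' @export
ARCHETYPE_NAMES <- c(
  "transient_up", "transient_down",
  "sustained_up", "sustained_down",
  "late_up_long_only", "late_down_long_only",
  "long_selective_up"
)

#' Timepoints (hours) of the screen design
#' @export
TIMEPOINTS <- c(2, 24)

new_archetype <- function(name, short_2, long_2, short_24, long_24) {
  template <- matrix(
    0, nrow = 4L, ncol = 2L,
    dimnames = list(TREATMENT_CLASSES, as.character(TIMEPOINTS))
  )
  template["short_acting", ] <- c(short_2, short_24)
  template["long_acting", ] <- c(long_2, long_24)
  template["intermediate", ] <- (template["short_acting", ] +
                                   template["long_acting", ]) / 2
  structure(list(name = name, template = template), class = "archetype")
}

#' Build the archetype template set
#'
#' @return A named list of 7 `archetype` objects, each with a `name` and a
#'   4 x 2 `template` matrix (treatment class x time in hours) of expected
#'   mean log2 deviations from vehicle for a unit effect size. Vehicle rows
#'   are exactly zero and intermediate rows are midpoints of the short- and
#'   long-acting rows.
#' @examples
#' tpl <- make_archetype_templates()
#' tpl$transient_up$template
#' @export
make_archetype_templates <- function() {
  arch <- list(
    new_archetype("transient_up",         1,    1.5,  0,    0),
    new_archetype("transient_down",      -1,   -1.5,  0,    0),
    new_archetype("sustained_up",         1.5,  0.75, 0,    1.5),
    new_archetype("sustained_down",      -1.5, -0.75, 0,   -1.5),
    new_archetype("late_up_long_only",    0,    0,    0,    1),
    new_archetype("late_down_long_only",  0,    0,    0,   -1),
    new_archetype("long_selective_up",    0,    1,    0,    0.75)
  )
  names(arch) <- vapply(arch, `[[`, character(1), "name")
  arch
}

# flatten a template to the canonical cell vector (class x time), used for
# pattern labeling correlations
template_cells <- function(template) {
  cells <- as.vector(template)
  names(cells) <- as.vector(outer(rownames(template), colnames(template),
                                  function(a, b) paste0(a, "@", b)))
  cells
}
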