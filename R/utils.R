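#' Main checklist categories
#'
#' The four main categories every checklist attribute falls under, in
#' canonical order: analytical validity (assay performance, specimen
#' handling, experimental rigor), clinical validity (study design and
#' statistical evaluation of the biomarker-outcome link), clinical utility
#' (real-world value: cost-effectiveness, feasibility, guideline approval),
#' and rationale (the unmet clinical need).
#'
#' @return Character vector of category tokens.
#' @export
#' @examples
#' bm_categories()
bm_categories <- function() {
  c("analytical_validity", "clinical_validity", "clinical_utility",
    "rationale")
}

#' Recognised publication study types
#'
#' `"clinical"` denotes ordinary clinical biomarker studies; the remaining
#' types are the additional, non-clinical study types whose presence for a
#' biomarker signals translational breadth.
#'
#' @return Character vector of study-type tokens.
#' @seealso [bm_amendable_types()] for the subset that amends the
#'   clinical-utility score.
#' @export
bm_study_types <- function() {
  c("clinical", "analytical_validation", "cost_effectiveness",
    "clinical_usefulness", "feasibility", "human_factor",
    "implementation", "decisional_analysis")
}

#' Study types that amend the clinical-utility score
#'
#' The six non-clinical study types whose presence for a biomarker pushes
#' its clinical-utility score upward: cost-effectiveness, clinical
#' usefulness, feasibility, human factor, implementation, and decisional
#' analysis. Clinical studies form the scored corpus itself and assay
#' (analytical) validation studies speak to analytical rather than clinical
#' utility, so neither amends.
#'
#' @return Character vector of study-type tokens.
#' @export
bm_amendable_types <- function() {
  setdiff(bm_study_types(), c("clinical", "analytical_validation"))
}

# Half-up rounding: percentages are reported at 2 dp with ties away from
# zero (base round() uses banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with the global RNG seeded (if seed non-NULL), restoring the
# caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_bm <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_bm(what, " must be numeric in [0, 1]")
  invisible(x)
}
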