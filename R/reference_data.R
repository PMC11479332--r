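#' Reference tables from the original bed-reaction-force study
#'
#' Small plain-text tables shipped with the package: the anthropometrics of
#' the 18-participant reference cohort (heights and weights; ages withheld
#' at source), the composition of the study's datasets (sample counts per
#' source and phase), and the published Phase One / Phase Two F1 and
#' accuracy scores of the best-performing classifier. They parameterise the
#' synthetic cohort generator and the bookkeeping/composition checks; the
#' underlying human recordings were never released.
#'
#' @return Each accessor returns a data.frame.
#' @export
cohort_demographics <- function() {
  utils::read.csv(system.file("extdata", "cohort_demographics.csv",
                              package = "bedpose"))
}

#' @rdname cohort_demographics
#' @export
dataset_composition <- function() {
  utils::read.csv(system.file("extdata", "dataset_composition.csv",
                              package = "bedpose"))
}

#' @rdname cohort_demographics
#' @export
published_phase_scores <- function() {
  utils::read.csv(system.file("extdata", "published_phase_scores.csv",
                              package = "bedpose"))
}
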