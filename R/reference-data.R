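#' Published clinical validation pairs
#'
#' The 34 calculated-versus-expert pattern-vector pairs from the
#' clinical validation study of the profiling method, as printed (3
#' decimals): for each respondent the calculated vector, the
#' psychologist's vector, the printed cosine similarity and the
#' reported number of per-question disagreements. Useful as a reference
#' set for checking the similarity pipeline against published values.
#'
#' @return Tibble with columns `respondent_id`, `calc_adaptive`,
#'   `calc_reactive`, `calc_creative`, `exp_adaptive`, `exp_reactive`,
#'   `exp_creative`, `similarity`, `disagreements`.
#' @export
clinical_validation_pairs <- function() {
  path <- system.file("extdata", "clinical_validation_pairs.csv",
                      package = "mfpattern", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$respondent_id <- as.character(out$respondent_id)
  as_tibble(out)
}

#' Published debt-negotiation prediction results
#'
#' The reported evaluation of the nearest-neighbour decision model on
#' the debt-negotiation cohort (1,204 debtors): per decision variable,
#' its class enumeration and count, the random-choice baseline, the
#' model success rate, the gain over random, and macro-averaged
#' precision and recall. These figures depend on the study's private
#' dataset and unpublished hyperparameters; the package ships them as
#' printed so its arithmetic (baselines, gains) can be checked against
#' them.
#'
#' @return Tibble with columns `decision_variable`, `enumeration`
#'   (pipe-separated class labels), `n_classes`, `random_rate`,
#'   `success_rate`, `gain`, `accuracy`, `macro_precision`,
#'   `macro_recall`.
#' @export
debt_negotiation_results <- function() {
  path <- system.file("extdata", "debt_negotiation_results.csv",
                      package = "mfpattern", mustWork = TRUE)
  as_tibble(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}
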