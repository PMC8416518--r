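#' Plot a membership-function set
#'
#' Draws the three pertinence functions of a fuzzifier set over the
#' 1-10 response scale.
#'
#' @param fuzzifier Per-pattern list of `mfp_membership` functions
#'   (e.g. `default_fuzzifiers()$default`).
#' @param step Grid step on the response scale.
#' @return A ggplot object.
#' @export
plot_membership <- function(fuzzifier, step = 0.05) {
  grid <- seq(1, 10, by = step)
  df <- purrr::map_dfr(PATTERNS, function(p) {
    tibble(response = grid, pattern = p,
           degree = evaluate_membership(fuzzifier[[p]], grid))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$degree,
                                   colour = .data$pattern)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "response (1-10)", y = "membership degree",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' @describeIn similarity_report Per-respondent similarity plot with the
#'   acceptance threshold.
#' @param object An `mfp_similarity_report`.
#' @method autoplot mfp_similarity_report
#' @export
autoplot.mfp_similarity_report <- function(object, ...) {
  df <- as_tibble(object)
  df$respondent_id <- factor(df$respondent_id,
                             levels = unique(df$respondent_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$respondent_id,
                                   y = .data$similarity,
                                   fill = .data$accepted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "respondent", y = "cosine similarity",
                  fill = "accepted") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn evaluate_model Success rate versus random baseline per
#'   decision variable.
#' @param object An `mfp_evaluation` tibble.
#' @param ... Unused.
#' @method autoplot mfp_evaluation
#' @export
autoplot.mfp_evaluation <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("success_rate", "random_rate"),
                            names_to = "rate", values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decision_variable,
                                   y = .data$percent, fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "decision variable", y = "success rate (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ternary-free profile plot
#'
#' Stacked composition of each respondent's pattern vector.
#'
#' @param profiles Output of [profile_respondents()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  df <- tidyr::pivot_longer(as_tibble(profiles), cols = dplyr::all_of(PATTERNS),
                            names_to = "pattern", values_to = "proportion")
  df$respondent_id <- factor(df$respondent_id,
                             levels = unique(df$respondent_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$respondent_id,
                                   y = .data$proportion,
                                   fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "respondent", y = "proportion", fill = "pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
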