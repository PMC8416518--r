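#' Fuzzify a single response
#'
#' Maps one 1-10 response to its degrees of fit with the three
#' behavioural patterns. When the metric is reverse-keyed, the response
#' is first mirrored (`r -> 11 - r`) so that every membership function
#' can be written in one canonical direction.
#'
#' @param response Integer response in 1..10.
#' @param fuzzifier A per-pattern list of `mfp_membership` functions, as
#'   returned by [fuzzifier_for()].
#' @param reversed Is the metric reverse-keyed?
#' @return Named numeric vector `c(adaptive =, reactive =, creative =)`,
#'   each in \[0, 1\].
#' @export
fuzzify_response <- function(response, fuzzifier, reversed = FALSE) {
  if (length(response) != 1 || is.na(response) || response != round(response) ||
      response < 1 || response > 10) {
    abort("response must be a single integer in 1..10",
          class = "mfp_domain_error")
  }
  r <- if (isTRUE(reversed)) 11 - response else response
  vapply(PATTERNS, function(p) evaluate_membership(fuzzifier[[p]], r),
         numeric(1))
}

#' Fuzzify response sheets
#'
#' Applies the catalog's membership functions to every response in a
#' long-form response table, yielding one fuzzy triple per answered
#' question.
#'
#' @param responses Tibble with columns `respondent_id`, `metric_id`,
#'   `response` (integers 1..10).
#' @param catalog An `mfp_catalog`; supplies per-metric fuzzifiers and
#'   reverse-keying flags. Metrics absent from the catalog raise an
#'   error.
#' @return Tibble with columns `respondent_id`, `metric_id`, `adaptive`,
#'   `reactive`, `creative`.
#' @export
fuzzify_sheets <- function(responses, catalog) {
  stopifnot(inherits(catalog, "mfp_catalog"))
  responses <- as_tibble(responses)
  unknown <- setdiff(unique(responses$metric_id), catalog$metrics$metric_id)
  if (length(unknown) > 0) {
    abort(paste0("responses reference metrics not in the catalog: ",
                 paste(unknown, collapse = ", ")),
          class = "mfp_validation_error")
  }
  r <- responses$response
  if (any(is.na(r)) || any(r != round(r)) || any(r < 1) || any(r > 10)) {
    abort("responses must be integers in 1..10", class = "mfp_domain_error")
  }
  rev_flag <- setNames(catalog$metrics$reversed, catalog$metrics$metric_id)
  degrees <- matrix(0, nrow(responses), 3, dimnames = list(NULL, PATTERNS))
  for (m in unique(responses$metric_id)) {
    rows <- which(responses$metric_id == m)
    x <- if (rev_flag[[m]]) 11 - r[rows] else r[rows]
    fz <- fuzzifier_for(catalog, m)
    for (p in PATTERNS) {
      degrees[rows, p] <- evaluate_membership(fz[[p]], x)
    }
  }
  dplyr::bind_cols(
    responses[, c("respondent_id", "metric_id")],
    as_tibble(degrees)
  )
}

#' Aggregate fuzzy triples into a pattern vector
#'
#' Sums the per-question degrees component-wise and divides by the grand
#' total, so the result is a normalized (adaptive, reactive, creative)
#' proportion vector summing to 1.
#'
#' @param triples Matrix or data frame with columns `adaptive`,
#'   `reactive`, `creative`, one row per answered question (or a single
#'   named triple).
#' @param degenerate What to do when every degree is zero: `"error"`
#'   (default) or `"uniform"` to return `(1/3, 1/3, 1/3)` with a
#'   `degenerate` attribute set.
#' @return Named numeric pattern vector summing to 1.
#' @export
aggregate_profile <- function(triples, degenerate = c("error", "uniform")) {
  degenerate <- match.arg(degenerate)
  if (is.null(dim(triples))) {
    triples <- matrix(triples, nrow = 1,
                      dimnames = list(NULL, names(triples) %||% PATTERNS))
  }
  m <- as.matrix(as.data.frame(triples)[, PATTERNS, drop = FALSE])
  if (nrow(m) == 0) {
    abort("at least one fuzzy triple is required", class = "mfp_domain_error")
  }
  if (any(m < 0) || any(m > 1)) {
    abort("membership degrees must lie in [0, 1]", class = "mfp_domain_error")
  }
  sums <- colSums(m)
  total <- sum(sums)
  if (total == 0) {
    if (degenerate == "uniform") {
      v <- setNames(rep(1 / 3, 3), PATTERNS)
      attr(v, "degenerate") <- TRUE
      return(v)
    }
    abort("all membership degrees are zero; profile is degenerate",
          class = "mfp_degenerate_error")
  }
  setNames(sums / total, PATTERNS)
}

#' Dominant pattern of a profile
#'
#' Returns the pattern with the largest component. Exact ties are broken
#' in the fixed order adaptive, reactive, creative (first wins) and
#' flagged via the `tie` attribute.
#'
#' @param v Named (or positionally adaptive/reactive/creative) numeric
#'   vector of three non-negative components, not all zero.
#' @return Length-one character vector (`"adaptive"`, `"reactive"` or
#'   `"creative"`) with attribute `tie` (logical).
#' @export
dominant_pattern <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3 || any(is.na(v)) || any(v < 0) || sum(v) == 0) {
    abort("pattern vector must be three non-negative components, not all zero",
          class = "mfp_degenerate_error")
  }
  i <- which.max(v)  # which.max takes the first maximum: the tie-break order
  out <- PATTERNS[[i]]
  attr(out, "tie") <- sum(v == max(v)) > 1
  out
}

#' Profile respondents from their response sheets
#'
#' The main profiling pipeline: fuzzifies every response with the
#' catalog's membership functions and aggregates each respondent's
#' triples into a normalized mental-functioning-pattern vector.
#'
#' @inheritParams fuzzify_sheets
#' @param driver_id Optional driver; when given, each respondent's sheet
#'   is validated against that driver's questionnaire and violations
#'   raise an error naming the respondent.
#' @param degenerate Passed to [aggregate_profile()].
#' @return Tibble with columns `respondent_id`, `adaptive`, `reactive`,
#'   `creative`, `dominant`, `tie`, `degenerate`, one row per
#'   respondent, in first-appearance order.
#' @examples
#' catalog <- default_catalog()
#' sheets <- tibble::tibble(
#'   respondent_id = "r1",
#'   metric_id = metrics_for_driver(catalog, "debt_collection")$metric_id,
#'   response = c(2, 3, 6, 8, 5, 7, 9, 4, 6, 5)
#' )
#' profile_respondents(sheets, catalog, driver_id = "debt_collection")
#' @export
profile_respondents <- function(responses, catalog, driver_id = NULL,
                                degenerate = c("error", "uniform")) {
  degenerate <- match.arg(degenerate)
  responses <- as_tibble(responses)
  if (!is.null(driver_id)) {
    expected <- metrics_for_driver(catalog, driver_id)
    for (id in unique(responses$respondent_id)) {
      sheet <- responses[responses$respondent_id == id, ]
      check <- validate_responses(sheet, expected)
      if (!check$ok) {
        abort(paste0("invalid sheet for respondent '", id, "': ",
                     paste(check$problems$problem, check$problems$metric_id,
                           collapse = "; ")),
              class = "mfp_validation_error")
      }
    }
  }
  fuzzy <- fuzzify_sheets(responses, catalog)
  ids <- unique(fuzzy$respondent_id)
  fac <- factor(fuzzy$respondent_id, levels = ids)
  sums <- rowsum(as.data.frame(fuzzy[, PATTERNS]), fac)
  totals <- rowSums(sums)
  if (any(totals == 0) && degenerate == "error") {
    abort(paste0("all membership degrees are zero for respondent(s): ",
                 paste(ids[totals == 0], collapse = ", ")),
          class = "mfp_degenerate_error")
  }
  v <- as.matrix(sums) / ifelse(totals == 0, 1, totals)
  deg <- totals == 0
  v[deg, ] <- 1 / 3
  doms <- apply(v, 1, function(x) as.character(dominant_pattern(x)))
  ties <- apply(v, 1, function(x) sum(x == max(x)) > 1)
  tibble(respondent_id = ids,
         adaptive = unname(v[, "adaptive"]),
         reactive = unname(v[, "reactive"]),
         creative = unname(v[, "creative"]),
         dominant = unname(doms), tie = unname(ties),
         degenerate = unname(deg))
}
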