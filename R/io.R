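#' Read response sheets from CSV or JSON
#'
#' The CSV form is long: a header `respondent_id,metric_id,response`
#' and one row per answered question. The JSON form is a map from
#' respondent id to a map from metric id to response. Malformed values
#' are rejected, never coerced: a non-integer or out-of-range response
#' aborts with its line number, as does a duplicated
#' (respondent, metric) pair.
#'
#' @param path Input file path.
#' @param format `"csv"` (default, long form) or `"json"`.
#' @return Tibble with columns `respondent_id`, `metric_id`, `response`
#'   (integer), in file order.
#' @export
read_response_sheets <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mfp_io_error")
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    needed <- c("respondent_id", "metric_id", "response")
    if (!all(needed %in% names(raw)) || nrow(raw) == 0) {
      abort(paste0("response sheet ", path,
                   " must have columns respondent_id,metric_id,response ",
                   "and at least one row"),
            class = "mfp_parse_error")
    }
    resp <- suppressWarnings(as.numeric(raw$response))
    bad <- which(is.na(resp) | resp != round(resp) | resp < 1 | resp > 10)
    if (length(bad) > 0) {
      abort(paste0("line ", bad[[1]] + 1, " of ", path,
                   ": response '", raw$response[[bad[[1]]]],
                   "' is not an integer in 1..10"),
            class = "mfp_parse_error")
    }
    key <- paste(raw$respondent_id, raw$metric_id)
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[[1]]
      abort(paste0("line ", i + 1, " of ", path,
                   ": duplicate response for (", raw$respondent_id[[i]],
                   ", ", raw$metric_id[[i]], ")"),
            class = "mfp_parse_error")
    }
    tibble(respondent_id = raw$respondent_id, metric_id = raw$metric_id,
           response = as.integer(resp))
  } else {
    doc <- jsonlite::read_json(path)
    rows <- purrr::imap(doc, function(answers, id) {
      tibble(respondent_id = id, metric_id = names(answers),
             response = as.numeric(unlist(answers)))
    })
    out <- dplyr::bind_rows(rows)
    bad <- which(out$response != round(out$response) |
                   out$response < 1 | out$response > 10)
    if (length(bad) > 0) {
      abort(paste0("respondent '", out$respondent_id[[bad[[1]]]],
                   "', metric '", out$metric_id[[bad[[1]]]],
                   "': response is not an integer in 1..10"),
            class = "mfp_parse_error")
    }
    out$response <- as.integer(out$response)
    out
  }
}

#' Write response sheets to long-form CSV
#'
#' @param sheets Tibble with `respondent_id`, `metric_id`, `response`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_sheets <- function(sheets, path) {
  readr::write_csv(as_tibble(sheets)[, c("respondent_id", "metric_id",
                                         "response")], path)
  invisible(path)
}

# half-up fixed-point formatting; the tables print 3 dp similarities,
# 2 dp rates and 4 dp gains
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_fixed <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}

#' Write respondent profiles to CSV
#'
#' Columns `respondent_id,adaptive,reactive,creative,dominant,flags`
#' with components printed to 3 decimals.
#'
#' @param profiles Output of [profile_respondents()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  profiles <- as_tibble(profiles)
  flags <- paste0(ifelse(profiles$tie, "tie", ""),
                  ifelse(profiles$degenerate, "degenerate", ""))
  out <- tibble(
    respondent_id = profiles$respondent_id,
    adaptive = format_fixed(profiles$adaptive, 3),
    reactive = format_fixed(profiles$reactive, 3),
    creative = format_fixed(profiles$creative, 3),
    dominant = profiles$dominant,
    flags = flags
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write reports to CSV with a JSON manifest
#'
#' `write_report()` dispatches on the report type. Similarity reports
#' are written with 3-decimal vector components and similarities plus
#' an `accepted` column; evaluation reports with 2-decimal rates and
#' 4-decimal gains. A sidecar manifest (`<path>.manifest.json`) records
#' the seed, a configuration hash and summary figures so a run can be
#' reproduced exactly.
#'
#' @param report An `mfp_similarity_report` or `mfp_evaluation` (or a
#'   row-bound tibble of evaluations).
#' @param path Output CSV path.
#' @param seed Seed recorded in the manifest, if any.
#' @param config Arbitrary configuration list hashed into the manifest.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  UseMethod("write_report")
}

#' @export
write_report.mfp_similarity_report <- function(report, path, seed = NULL,
                                               config = NULL) {
  cols3 <- c(paste0("calc_", PATTERNS), paste0("exp_", PATTERNS),
             "similarity")
  out <- as_tibble(report)
  for (cc in intersect(cols3, names(out))) {
    out[[cc]] <- format_fixed(out[[cc]], 3)
  }
  out$accepted <- as.integer(report$accepted)
  readr::write_csv(out, path)
  write_manifest(path, seed = seed, config = config,
                 summary = as.list(glance(report)))
  invisible(path)
}

#' @export
write_report.mfp_evaluation <- function(report, path, seed = NULL,
                                        config = NULL) {
  out <- as_tibble(report)
  for (cc in intersect(c("random_rate", "success_rate", "accuracy",
                         "macro_precision", "macro_recall"), names(out))) {
    out[[cc]] <- format_fixed(out[[cc]], 2)
  }
  out$gain <- format_fixed(report$gain, 4)
  readr::write_csv(out, path)
  write_manifest(path, seed = seed, config = config,
                 summary = list(n_variables = nrow(report)))
  invisible(path)
}

write_manifest <- function(path, seed = NULL, config = NULL,
                           summary = NULL) {
  manifest <- list(
    file = basename(path),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config),
    summary = summary
  )
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Read and write labelled decision datasets
#'
#' A labelled dataset has a `respondent_id` column, numeric feature
#' columns, and a categorical `decision` column.
#'
#' @param path CSV path.
#' @return `read_labeled_dataset()`: a tibble; the `decision` column is
#'   read as character.
#' @export
read_labeled_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mfp_io_error")
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("respondent_id", "decision") %in% names(out))) {
    abort("labelled dataset needs respondent_id and decision columns",
          class = "mfp_parse_error")
  }
  out$decision <- as.character(out$decision)
  out$respondent_id <- as.character(out$respondent_id)
  as_tibble(out)
}

#' @rdname read_labeled_dataset
#' @param dataset Tibble to write.
#' @export
write_labeled_dataset <- function(dataset, path) {
  readr::write_csv(as_tibble(dataset), path)
  invisible(path)
}

#' Reshape long sheets into a feature matrix
#'
#' Turns long-form responses into one row per respondent with one
#' numeric column per question (the raw-response feature encoding used
#' by the decision model), ordered by the driver's questionnaire.
#'
#' @param sheets Long tibble (`respondent_id`, `metric_id`, `response`).
#' @param metric_ids Questionnaire order; default the metrics present,
#'   in first appearance order.
#' @return Wide tibble: `respondent_id` plus one column per metric.
#' @export
responses_to_features <- function(sheets, metric_ids = NULL) {
  sheets <- as_tibble(sheets)
  if (is.null(metric_ids)) metric_ids <- unique(sheets$metric_id)
  wide <- tidyr::pivot_wider(sheets, id_cols = "respondent_id",
                             names_from = "metric_id",
                             values_from = "response")
  wide[, c("respondent_id", metric_ids)]
}
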