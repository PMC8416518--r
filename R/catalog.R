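#' Questionnaire catalog
#'
#' A catalog bundles everything needed to run a profiling questionnaire:
#' the *metrics* (one per behavioural characteristic, each with its
#' question text, linguistic anchors and a `primary`/`circumstantial`
#' category), the *drivers* (named analysis contexts that select an
#' ordered subset of circumstantial metrics and append the primary
#' metrics relevant to that context), and the set of fuzzy membership
#' functions used to score responses (see [default_fuzzifiers()]).
#'
#' Primary metrics capture universal, innate characteristics (anxiety,
#' self-esteem, ...) and are candidates for every questionnaire;
#' circumstantial metrics capture context-dependent social
#' characteristics (financial literacy, impulsiveness, ...) and are
#' selected per driver.
#'
#' @param metrics Tibble with columns `metric_id`, `name`, `category`
#'   (`"primary"` or `"circumstantial"`), `question_text`,
#'   `anchor_left`, `anchor_center`, `anchor_right`, `reversed`.
#' @param drivers Tibble with columns `driver_id`, `name`,
#'   `circumstantial` (list column of metric ids), `primary`
#'   (list column of metric ids appended after the circumstantial ones).
#' @param fuzzifiers Named list of per-metric fuzzifier sets; must
#'   contain a `default` entry (see [make_fuzzifier()]).
#'
#' @return An object of class `mfp_catalog`.
#' @seealso [default_catalog()], [load_catalog()], [metrics_for_driver()]
#' @export
new_catalog <- function(metrics, drivers, fuzzifiers = default_fuzzifiers()) {
  metrics <- as_tibble(metrics)
  drivers <- as_tibble(drivers)
  required <- c("metric_id", "name", "category", "question_text",
                "anchor_left", "anchor_center", "anchor_right", "reversed")
  missing <- setdiff(required, names(metrics))
  if (length(missing) > 0) {
    abort(paste0("catalog metrics are missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "mfp_validation_error")
  }
  if (anyDuplicated(metrics$metric_id)) {
    dup <- unique(metrics$metric_id[duplicated(metrics$metric_id)])
    abort(paste0("duplicate metric_id in catalog: ",
                 paste(dup, collapse = ", ")),
          class = "mfp_validation_error")
  }
  bad_cat <- setdiff(unique(metrics$category), c("primary", "circumstantial"))
  if (length(bad_cat) > 0) {
    abort(paste0("metric category must be 'primary' or 'circumstantial', got: ",
                 paste(bad_cat, collapse = ", ")),
          class = "mfp_validation_error")
  }
  for (i in seq_len(nrow(drivers))) {
    drv <- drivers$driver_id[[i]]
    circ <- drivers$circumstantial[[i]]
    prim <- drivers$primary[[i]]
    # interest lists may name metrics of either category (the published
    # driver tables do, e.g. beliefs under debt collection), but appended
    # primary metrics must really be primary
    check_driver_refs(drv, circ, metrics, category = NULL)
    check_driver_refs(drv, prim, metrics, category = "primary")
    combined <- c(circ, prim)
    if (anyDuplicated(combined)) {
      abort(paste0("driver '", drv, "' lists metric '",
                   combined[duplicated(combined)][[1]], "' more than once"),
            class = "mfp_integrity_error")
    }
  }
  if (!is.list(fuzzifiers) || is.null(fuzzifiers$default)) {
    abort("fuzzifiers must be a named list with a 'default' entry",
          class = "mfp_validation_error")
  }
  structure(
    list(metrics = metrics, drivers = drivers, fuzzifiers = fuzzifiers),
    class = "mfp_catalog"
  )
}

check_driver_refs <- function(driver_id, ids, metrics, category = NULL) {
  unknown <- setdiff(ids, metrics$metric_id)
  if (length(unknown) > 0) {
    abort(paste0("driver '", driver_id, "' references unknown metric '",
                 unknown[[1]], "'"),
          class = "mfp_integrity_error")
  }
  if (!is.null(category)) {
    cats <- metrics$category[match(ids, metrics$metric_id)]
    wrong <- ids[cats != category]
    if (length(wrong) > 0) {
      abort(paste0("driver '", driver_id, "' lists metric '", wrong[[1]],
                   "' as ", category, " but the catalog says otherwise"),
            class = "mfp_integrity_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.mfp_catalog <- function(x, ...) {
  n_prim <- sum(x$metrics$category == "primary")
  cat("<mfp_catalog> ", nrow(x$metrics), " metrics (", n_prim, " primary, ",
      nrow(x$metrics) - n_prim, " circumstantial), ",
      nrow(x$drivers), " drivers\n", sep = "")
  invisible(x)
}

# The shipped questionnaire universe: 26 behavioural metrics (8 primary,
# 18 circumstantial) with their question text and linguistic anchors, and
# 7 analysis drivers. Only the beliefs item is visibly reverse-keyed
# (left anchor "Yes", right anchor "No"): responses to it are mapped
# r -> 11 - r before fuzzification so that every membership function can
# be written in one canonical direction.
default_metric_table <- function() {
  tribble_metric <- function(id, name, cat, q, l, c, r, rev = FALSE) {
    tibble(metric_id = id, name = name, category = cat, question_text = q,
           anchor_left = l, anchor_center = c, anchor_right = r,
           reversed = rev)
  }
  dplyr::bind_rows(
    tribble_metric("anxiety", "Anxiety", "primary",
      "Are you a person that is in a constant state of alert?",
      "No", "Sometimes", "Yes"),
    tribble_metric("self_discipline", "Self-discipline", "primary",
      "Do you consider yourself a disciplined and organized person to practice actions that lead to your goal?",
      "No", "It depends", "Yes"),
    tribble_metric("self_esteem", "Self-esteem", "primary",
      "Are you a person who recognizes your qualities and acts to express your feelings and behaviors?",
      "I do not recognize or act", "Sometimes I recognize and act",
      "I recognize and act"),
    tribble_metric("beliefs", "Beliefs", "primary",
      "When making decisions do you seek to base yourself on the values and habits learned in your family of origin?",
      "Yes", "Sometimes", "No", rev = TRUE),
    tribble_metric("cultural_empowerment", "Cultural empowerment", "primary",
      "In your opinion, does culture influence decision-making?",
      "No", "It depends", "Yes"),
    tribble_metric("cognitive_flexibility", "Cognitive flexibility", "primary",
      "How much capacity do you think you have to change your beliefs, paradigms, and values in the face of adversity?",
      "Low", "Medium", "High"),
    tribble_metric("cognitive_preservation", "Cognitive preservation", "primary",
      "Do you imagine that you have some difficulty to perceive and act in the face of obstacles of life?",
      "Yes", "Depends on the situation", "No"),
    tribble_metric("learned_resilience", "Learned resilience", "primary",
      "How much can you learn from your experiences?",
      "Little", "What is necessary", "Very"),
    tribble_metric("financial_literacy", "Financial literacy", "circumstantial",
      "Do you consider yourself a person who always balances your income/expenses against your needs?",
      "No", "Sometimes", "Yes"),
    tribble_metric("family_environment", "Family environment", "circumstantial",
      "How is money used, that is, the value it is given in your family of origin?",
      "Limited", "It depends", "Free"),
    tribble_metric("risk_attachment", "Risk attachment", "circumstantial",
      "Do you consider yourself a person who generally assesses the risk you face when facing challenges?",
      "No", "It depends", "Yes"),
    tribble_metric("assertiveness", "Assertiveness", "circumstantial",
      "Are you a person who recognizes your qualities and acts to express your feelings and behaviors?",
      "I do not recognize or act", "Sometimes I recognize and act",
      "I recognize and act"),
    tribble_metric("self_control", "Self-control", "circumstantial",
      "What do you use when making a decision?",
      "More emotion", "Emotion and reason", "More reason"),
    tribble_metric("self_image", "Self-image", "circumstantial",
      "Is the image you convey to people consistent and authentic with your real image?",
      "No", "It depends", "Yes"),
    tribble_metric("rational_numbness", "Rational numbness", "circumstantial",
      "In general, when you have to make a decision, do you try to make use of reason and emotion, or in most people do not worry about it?",
      "Emotion", "It depends", "Reason and emotion"),
    tribble_metric("affective_flexibility", "Affective flexibility", "circumstantial",
      "Can you see learning when you experience frustration, failure, or failure in your personal or professional life?",
      "No", "It depends", "Yes"),
    tribble_metric("degree_of_education", "Degree of education", "circumstantial",
      "Do you think that knowledge has been a source of growth in your personal and professional life?",
      "No", "It depends", "Yes"),
    tribble_metric("degree_of_experience", "Degree of experience", "circumstantial",
      "Do you imagine that a person with countless experiences has the capacity to make better choices for you?",
      "No", "It depends", "Yes"),
    tribble_metric("emotional_imbroglio", "Emotional imbroglio", "circumstantial",
      "In your opinion, do material, financial, and emotional difficulties experienced by a person interfere with decision-making?",
      "No", "It depends", "Yes"),
    tribble_metric("emotional_immunity", "Emotional immunity", "circumstantial",
      "Are you a person who seeks to learn from the experience of the other, when arguments of the other are well-founded, even if you have to give up your convictions?",
      "No", "It depends", "Yes"),
    tribble_metric("impulsiveness", "Impulsiveness", "circumstantial",
      "How do you assess your reaction to everyday issues?",
      "Elaborated", "It depends", "Immediate"),
    tribble_metric("chaotic_insensitivity", "Chaotic insensitivity", "circumstantial",
      "Do you usually notice something that has bothered you in a new environment and does something to change this situation?",
      "No", "It depends", "Yes"),
    tribble_metric("family_loyalty", "Family loyalty", "circumstantial",
      "Can a loyal person consciously make decisions with \"the eyes of family members?\"",
      "No", "It depends", "Yes"),
    tribble_metric("cerebral_plasticity", "Cerebral plasticity", "circumstantial",
      "In general, are you a person who accepts new information to make the necessary changes in order to change your quality of life?",
      "No", "It depends", "Yes"),
    tribble_metric("emotional_task_fulfilling", "Emotional task-fulfilling", "circumstantial",
      "In general, are you a person who recognizes and expresses your emotions in your activities as a whole?",
      "No", "It depends", "Yes"),
    tribble_metric("affective_transitivity", "Affective transitivity", "circumstantial",
      "Are you a person who moves between different groups using flexibility to get out and get into various interpretive roles?",
      "No", "It depends", "Yes")
  )
}

default_driver_table <- function() {
  tibble(
    driver_id = c("beneficiary_health_plan", "debt_collection",
                  "consumption_material_goods", "insurance_proposal",
                  "selection_process", "personal_professional_planning",
                  "personal_treatment"),
    name = c("Beneficiary evaluation of health plan", "Debt collection",
             "Consumption of material goods", "Insurance proposal",
             "Selection process", "Personal/professional planning",
             "Personal treatment"),
    circumstantial = list(
      c("family_environment", "risk_attachment", "beliefs",
        "degree_of_experience", "family_loyalty", "cerebral_plasticity"),
      c("financial_literacy", "family_environment", "assertiveness",
        "self_control", "beliefs", "impulsiveness"),
      c("financial_literacy", "family_environment", "assertiveness",
        "self_control", "self_esteem", "self_image", "rational_numbness",
        "affective_flexibility", "degree_of_education",
        "degree_of_experience", "emotional_imbroglio", "emotional_immunity",
        "impulsiveness", "chaotic_insensitivity", "cerebral_plasticity"),
      c("family_environment", "risk_attachment", "rational_numbness",
        "degree_of_education", "emotional_imbroglio"),
      c("assertiveness", "self_esteem", "self_image",
        "affective_flexibility", "degree_of_education",
        "degree_of_experience", "emotional_immunity", "impulsiveness",
        "chaotic_insensitivity", "cerebral_plasticity",
        "affective_transitivity"),
      c("assertiveness", "self_control", "self_esteem", "self_image",
        "beliefs", "affective_flexibility", "degree_of_education",
        "degree_of_experience", "emotional_imbroglio", "emotional_immunity",
        "impulsiveness", "chaotic_insensitivity", "cerebral_plasticity",
        "emotional_task_fulfilling", "affective_transitivity"),
      c("assertiveness", "self_esteem", "affective_flexibility",
        "degree_of_experience", "emotional_immunity", "family_loyalty",
        "cerebral_plasticity", "emotional_task_fulfilling",
        "affective_transitivity")
    ),
    primary = list(
      character(0),
      c("self_esteem", "self_discipline", "anxiety", "learned_resilience"),
      character(0),
      character(0),
      character(0),
      character(0),
      character(0)
    )
  )
}

#' Default questionnaire catalog
#'
#' Returns the catalog shipped with the package: 26 metrics (8 primary,
#' 18 circumstantial) and 7 circumstantial drivers, together with the
#' default membership-function set. The debt-collection driver carries
#' six circumstantial metrics plus four primary metrics (self-esteem,
#' self-discipline, anxiety, learned resilience), giving the 10-question
#' debt-negotiation form.
#'
#' @return An `mfp_catalog`.
#' @examples
#' cat <- default_catalog()
#' metrics_for_driver(cat, "debt_collection")
#' @export
default_catalog <- function() {
  new_catalog(default_metric_table(), default_driver_table(),
              default_fuzzifiers())
}

#' Select the questionnaire for a driver
#'
#' A driver names an analysis context (e.g. debt collection) and selects
#' its circumstantial metrics followed by the primary metrics attached
#' to that context, in configuration order. The result is the ordered
#' questionnaire for that context.
#'
#' @param catalog An `mfp_catalog`.
#' @param driver_id Driver identifier, e.g. `"debt_collection"`.
#' @return A tibble of metrics (same columns as `catalog$metrics`), one
#'   row per question, in questionnaire order.
#' @export
metrics_for_driver <- function(catalog, driver_id) {
  stopifnot(inherits(catalog, "mfp_catalog"))
  i <- match(driver_id, catalog$drivers$driver_id)
  if (is.na(i)) {
    abort(paste0("unknown driver '", driver_id, "'"),
          class = "mfp_lookup_error")
  }
  ids <- c(catalog$drivers$circumstantial[[i]], catalog$drivers$primary[[i]])
  catalog$metrics[match(ids, catalog$metrics$metric_id), ]
}

#' Validate a response sheet against an expected questionnaire
#'
#' Checks that a respondent's sheet answers exactly the expected metrics
#' with integer responses in 1..10. Violations are reported, not thrown,
#' so a batch of sheets can be screened and the failures inspected.
#'
#' @param responses Named numeric vector or single-respondent tibble with
#'   columns `metric_id` and `response`.
#' @param expected_metrics Tibble of metrics as returned by
#'   [metrics_for_driver()], or a character vector of metric ids.
#' @return A list with `ok` (logical) and `problems` (tibble with columns
#'   `metric_id`, `problem`, `value`).
#' @export
validate_responses <- function(responses, expected_metrics) {
  if (is.data.frame(expected_metrics)) {
    expected <- expected_metrics$metric_id
  } else {
    expected <- as.character(expected_metrics)
  }
  if (is.data.frame(responses)) {
    ids <- as.character(responses$metric_id)
    vals <- responses$response
  } else {
    ids <- names(responses)
    vals <- unname(responses)
  }
  problems <- list()
  add <- function(metric_id, problem, value = NA_real_) {
    problems[[length(problems) + 1]] <<-
      tibble(metric_id = metric_id, problem = problem, value = value)
  }
  for (m in setdiff(expected, ids)) add(m, "missing")
  for (m in setdiff(ids, expected)) add(m, "unexpected")
  dup <- unique(ids[duplicated(ids)])
  for (m in dup) add(m, "duplicate")
  keep <- ids %in% expected & !ids %in% dup
  for (j in which(keep)) {
    v <- vals[[j]]
    if (is.na(v) || v != round(v)) {
      add(ids[[j]], "non_integer", as.numeric(v))
    } else if (v < 1 || v > 10) {
      add(ids[[j]], "out_of_range", as.numeric(v))
    }
  }
  problems <- if (length(problems) == 0) {
    tibble(metric_id = character(), problem = character(), value = numeric())
  } else {
    dplyr::bind_rows(problems)
  }
  list(ok = nrow(problems) == 0, problems = problems)
}

#' Read a catalog from a YAML or JSON document
#'
#' The document must contain `metrics:` and `drivers:` sections and may
#' contain a `fuzzifiers:` section; see the shipped
#' `inst/extdata/catalog.yaml` for the schema. Referential integrity
#' between drivers and metrics is enforced on load.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mfp_catalog`.
#' @export
load_catalog <- function(path) {
  doc <- read_config_document(path)
  if (is.null(doc$metrics) || is.null(doc$drivers)) {
    abort("catalog document must have 'metrics' and 'drivers' sections",
          class = "mfp_validation_error")
  }
  metrics <- purrr::map_dfr(doc$metrics, function(m) {
    tibble(metric_id = m$metric_id, name = m$name, category = m$category,
           question_text = m$question_text %||% "",
           anchor_left = m$anchors[[1]], anchor_center = m$anchors[[2]],
           anchor_right = m$anchors[[3]],
           reversed = isTRUE(m$reversed))
  })
  drivers <- tibble(
    driver_id = purrr::map_chr(doc$drivers, "driver_id"),
    name = purrr::map_chr(doc$drivers, ~ .x$name %||% .x$driver_id),
    circumstantial = purrr::map(doc$drivers,
                                ~ as.character(unlist(.x$circumstantial))),
    primary = purrr::map(doc$drivers, ~ as.character(unlist(.x$primary)))
  )
  fuzz <- if (is.null(doc$fuzzifiers)) {
    default_fuzzifiers()
  } else {
    parse_fuzzifier_config(doc$fuzzifiers)
  }
  new_catalog(metrics, drivers, fuzz)
}

#' Write a catalog to YAML or JSON
#'
#' @param catalog An `mfp_catalog`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "mfp_catalog"))
  doc <- list(
    metrics = purrr::pmap(catalog$metrics, function(metric_id, name, category,
                                                    question_text, anchor_left,
                                                    anchor_center, anchor_right,
                                                    reversed) {
      list(metric_id = metric_id, name = name, category = category,
           question_text = question_text,
           anchors = list(anchor_left, anchor_center, anchor_right),
           reversed = reversed)
    }),
    drivers = purrr::pmap(catalog$drivers, function(driver_id, name,
                                                    circumstantial, primary) {
      list(driver_id = driver_id, name = name,
           circumstantial = as.list(circumstantial),
           primary = as.list(primary))
    }),
    fuzzifiers = fuzzifier_config(catalog$fuzzifiers)
  )
  write_config_document(doc, path)
  invisible(path)
}

read_config_document <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mfp_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort(paste0("unsupported config format: .", ext), class = "mfp_io_error")
  }
}

write_config_document <- function(doc, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    abort(paste0("unsupported config format: .", ext), class = "mfp_io_error")
  }
  invisible(path)
}
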