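#' Respondent archetypes
#'
#' An archetype describes a sub-population of respondents by a Dirichlet
#' concentration over the three patterns and a response-noise level on
#' the 1-10 answer scale. The three defaults mirror the three-pattern
#' taxonomy with one clearly dominant component each (concentrations
#' (8, 1, 1), (1, 8, 1), (1, 1, 8)), giving well-separated
#' sub-populations whose separation can be relaxed by flattening the
#' weights.
#'
#' @param name Archetype name.
#' @param pattern_weights Strictly positive Dirichlet concentration
#'   triple (adaptive, reactive, creative).
#' @param response_noise_sd Standard deviation, in scale points, of the
#'   Gaussian jitter added to each ideal answer; default 1 (about one
#'   scale point of answer inconsistency).
#' @return An object of class `mfp_archetype`.
#' @export
archetype <- function(name, pattern_weights, response_noise_sd = 1) {
  pattern_weights <- as.numeric(pattern_weights)
  if (length(pattern_weights) != 3 || any(pattern_weights <= 0)) {
    abort("pattern_weights must be three strictly positive values",
          class = "mfp_config_error")
  }
  if (response_noise_sd < 0) {
    abort("response_noise_sd must be non-negative",
          class = "mfp_config_error")
  }
  structure(list(name = name, pattern_weights = pattern_weights,
                 response_noise_sd = response_noise_sd),
            class = "mfp_archetype")
}

#' @rdname archetype
#' @param response_noise_sd Passed to each default archetype.
#' @export
default_archetypes <- function(response_noise_sd = 1) {
  list(
    archetype("adaptive", c(8, 1, 1), response_noise_sd),
    archetype("reactive", c(1, 8, 1), response_noise_sd),
    archetype("creative", c(1, 1, 8), response_noise_sd)
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Generate synthetic response sheets
#'
#' Draws each respondent's true pattern vector from their archetype's
#' Dirichlet distribution, then answers each question of the driver's
#' questionnaire with the integer response whose fuzzy triple is most
#' similar (by cosine) to the true vector, plus rounded Gaussian noise
#' clipped to \[1, 10\]. Responses with an all-zero fuzzy triple carry
#' no pattern signal and are never chosen as the ideal answer.
#'
#' @param catalog An `mfp_catalog`.
#' @param driver_id Driver selecting the questionnaire.
#' @param n Number of respondents.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @param archetypes List of [archetype()] objects.
#' @param mix Mixing proportions over the archetypes, summing to 1;
#'   default uniform.
#' @return List with `sheets` (long tibble `respondent_id`, `metric_id`,
#'   `response`) and `true_vectors` (tibble `respondent_id`,
#'   `archetype`, `adaptive`, `reactive`, `creative`).
#' @export
generate_responses <- function(catalog, driver_id, n, seed,
                               archetypes = default_archetypes(),
                               mix = NULL) {
  stopifnot(inherits(catalog, "mfp_catalog"))
  if (length(archetypes) == 0) {
    abort("at least one archetype is required", class = "mfp_config_error")
  }
  if (is.null(mix)) mix <- rep(1 / length(archetypes), length(archetypes))
  if (length(mix) != length(archetypes) || abs(sum(mix) - 1) > 1e-9) {
    abort("mix proportions must match the archetypes and sum to 1",
          class = "mfp_config_error")
  }
  metrics <- metrics_for_driver(catalog, driver_id)
  ids <- sprintf("r%04d", seq_len(n))
  with_local_seed(seed, {
    arch_idx <- sample.int(length(archetypes), n, replace = TRUE, prob = mix)
    v <- matrix(0, n, 3, dimnames = list(NULL, PATTERNS))
    for (a in seq_along(archetypes)) {
      rows <- which(arch_idx == a)
      if (length(rows) > 0) {
        v[rows, ] <- rdirichlet(length(rows),
                                archetypes[[a]]$pattern_weights)
      }
    }
    noise_sd <- vapply(archetypes, function(a) a$response_noise_sd,
                       numeric(1))[arch_idx]
    responses <- matrix(0L, n, nrow(metrics))
    for (j in seq_len(nrow(metrics))) {
      cand <- candidate_triples(catalog, metrics$metric_id[[j]],
                                metrics$reversed[[j]])
      norms <- sqrt(rowSums(cand^2))
      score <- (cand %*% t(v)) / pmax(norms, .Machine$double.eps)
      score[norms == 0, ] <- -Inf
      ideal <- apply(score, 2, which.max)
      noisy <- round(ideal + rnorm(n, sd = noise_sd))
      responses[, j] <- as.integer(pmin(10, pmax(1, noisy)))
    }
    sheets <- tibble(
      respondent_id = rep(ids, each = nrow(metrics)),
      metric_id = rep(metrics$metric_id, times = n),
      response = as.integer(t(responses))
    )
    true_vectors <- dplyr::bind_cols(
      tibble(respondent_id = ids,
             archetype = vapply(archetypes, function(a) a$name,
                                character(1))[arch_idx]),
      as_tibble(v)
    )
    list(sheets = sheets, true_vectors = true_vectors)
  })
}

# fuzzy triples of every integer response 1..10 for one metric
candidate_triples <- function(catalog, metric_id, reversed) {
  fz <- fuzzifier_for(catalog, metric_id)
  t(vapply(1:10, function(r) fuzzify_response(r, fz, reversed), numeric(3)))
}

#' Generate expert ratings for true pattern vectors
#'
#' Emulates an expert scoring each pattern on a small integer scale:
#' the true vector is perturbed with Gaussian noise, converted to
#' integer scores in 1..`integer_scale_max` per pattern, and normalized
#' to sum 1. With zero noise, vectors exactly representable on the
#' integer scale are reproduced exactly.
#'
#' @param true_vectors Tibble (or matrix) with `adaptive`, `reactive`,
#'   `creative` columns.
#' @param integer_scale_max Top of the expert's integer scale,
#'   default 10.
#' @param noise_sd Perturbation standard deviation on the proportion
#'   scale, default 0.05.
#' @param seed Integer seed.
#' @return Tibble with `adaptive`, `reactive`, `creative` columns (plus
#'   `respondent_id` if present in the input), each row summing to 1.
#' @export
generate_expert_ratings <- function(true_vectors, integer_scale_max = 10,
                                    noise_sd = 0.05, seed = 1L) {
  if (integer_scale_max < 1) {
    abort("integer_scale_max must be at least 1", class = "mfp_config_error")
  }
  v <- as.matrix(as.data.frame(true_vectors)[, PATTERNS])
  with_local_seed(seed, {
    pert <- v + matrix(rnorm(length(v), sd = noise_sd), nrow(v))
    pert <- pmax(pert, 0)
    scores <- pmax(round(pert * integer_scale_max), 1)
    out <- as_tibble(scores / rowSums(scores))
  })
  if (is.data.frame(true_vectors) && "respondent_id" %in% names(true_vectors)) {
    out <- dplyr::bind_cols(true_vectors["respondent_id"], out)
  }
  out
}

#' Declare a deterministic decision rule
#'
#' The default rule scores each true pattern vector with a linear
#' combination of its components and assigns classes by equal-mass
#' quantile bins of that score over the cohort. The default weights
#' (0, 0.5, 1) order respondents along an adaptive-to-creative gradient.
#'
#' @param weights Length-3 numeric weights over (adaptive, reactive,
#'   creative).
#' @return An object of class `mfp_decision_rule`.
#' @export
decision_rule <- function(weights = c(0, 0.5, 1)) {
  weights <- as.numeric(weights)
  if (length(weights) != 3 || any(is.na(weights))) {
    abort("rule weights must be three numeric values",
          class = "mfp_config_error")
  }
  structure(list(weights = weights), class = "mfp_decision_rule")
}

#' Generate decision labels coupled to the pattern vectors
#'
#' Applies a deterministic rule mapping each true vector to one of the
#' variable's classes, then flips each label to a uniformly chosen
#' *other* class with probability `label_noise`.
#'
#' @param true_vectors Tibble or matrix with `adaptive`, `reactive`,
#'   `creative` columns.
#' @param variable An `mfp_decision_variable`.
#' @param rule An `mfp_decision_rule`; default [decision_rule()].
#' @param label_noise Flip probability in \[0, 1\], default 0.
#' @param seed Integer seed.
#' @return Character vector of labels from the variable's enumeration.
#' @export
generate_decisions <- function(true_vectors, variable,
                               rule = decision_rule(), label_noise = 0,
                               seed = 1L) {
  stopifnot(inherits(variable, "mfp_decision_variable"),
            inherits(rule, "mfp_decision_rule"))
  if (label_noise < 0 || label_noise > 1) {
    abort("label_noise must lie in [0, 1]", class = "mfp_config_error")
  }
  v <- as.matrix(as.data.frame(true_vectors)[, PATTERNS])
  score <- drop(v %*% rule$weights)
  k <- variable$n_classes
  # equal-mass bins via ranks; ties resolved by row order, deterministic
  bin <- ceiling(rank(score, ties.method = "first") * k / length(score))
  labels <- variable$classes[bin]
  if (label_noise > 0) {
    labels <- with_local_seed(seed, {
      flip <- runif(length(labels)) < label_noise
      if (any(flip)) {
        labels[flip] <- vapply(labels[flip], function(l) {
          sample(setdiff(variable$classes, l), 1)
        }, character(1))
      }
      labels
    })
  }
  labels
}

#' Default synthetic decision variables
#'
#' Four categorical outcomes of a simulated debt negotiation, spanning
#' 3 to 6 classes: the negotiation stance, the accepted discount tier,
#' the number of installments agreed, and the number actually paid.
#' All have at least three classes so that the gain over the random
#' baseline remains an informative signal-recovery measure (a binary
#' outcome caps the attainable gain at 2).
#'
#' @return Named list of `mfp_decision_variable` objects.
#' @export
default_decision_variables <- function() {
  list(
    negotiation_stance = decision_variable(
      "negotiation_stance", c("refuse", "negotiate", "settle")),
    discount_tier = decision_variable(
      "discount_tier", c("0", "25", "50", "75")),
    installments = decision_variable(
      "installments", as.character(1:6)),
    installments_paid = decision_variable(
      "installments_paid", as.character(0:4))
  )
}

#' Simulate a complete cohort
#'
#' End-to-end generator: response sheets, true pattern vectors, expert
#' ratings and decision labels for every default decision variable, all
#' reproducible from one seed.
#'
#' @inheritParams generate_responses
#' @param expert_noise_sd Passed to [generate_expert_ratings()].
#' @param variables Named list of `mfp_decision_variable`s; default
#'   [default_decision_variables()].
#' @param rule Decision rule shared by the variables.
#' @param label_noise Flip probability applied to every variable.
#' @return List of class `mfp_cohort` with elements `sheets`,
#'   `true_vectors`, `expert_vectors`, `decisions` (tibble with
#'   `respondent_id` plus one column per variable), and `seed`.
#' @export
simulate_cohort <- function(catalog, driver_id, n, seed,
                            archetypes = default_archetypes(), mix = NULL,
                            expert_noise_sd = 0.05,
                            variables = default_decision_variables(),
                            rule = decision_rule(), label_noise = 0) {
  gen <- generate_responses(catalog, driver_id, n, seed,
                            archetypes = archetypes, mix = mix)
  expert <- generate_expert_ratings(gen$true_vectors,
                                    noise_sd = expert_noise_sd,
                                    seed = seed + 1L)
  decisions <- tibble(respondent_id = gen$true_vectors$respondent_id)
  for (i in seq_along(variables)) {
    decisions[[variables[[i]]$name]] <-
      generate_decisions(gen$true_vectors, variables[[i]], rule = rule,
                         label_noise = label_noise, seed = seed + 1L + i)
  }
  structure(list(sheets = gen$sheets, true_vectors = gen$true_vectors,
                 expert_vectors = expert, decisions = decisions,
                 seed = seed),
            class = "mfp_cohort")
}

#' @export
print.mfp_cohort <- function(x, ...) {
  cat("<mfp_cohort> ", nrow(x$true_vectors), " respondents, ",
      length(unique(x$sheets$metric_id)), " questions, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Corrupt answers in generated sheets
#'
#' Replaces `q` randomly chosen answers per respondent with uniform
#' random responses in 1..10, emulating inconsistent answering. Used to
#' study how answer corruption degrades similarity to expert ratings.
#'
#' @param sheets Long response tibble (`respondent_id`, `metric_id`,
#'   `response`).
#' @param q Number of answers to corrupt per respondent (0 to the
#'   questionnaire length).
#' @param seed Integer seed.
#' @return Corrupted copy of `sheets`.
#' @export
corrupt_responses <- function(sheets, q, seed) {
  sheets <- as_tibble(sheets)
  if (q == 0) return(sheets)
  with_local_seed(seed, {
    for (id in unique(sheets$respondent_id)) {
      rows <- which(sheets$respondent_id == id)
      pick <- sample(rows, min(q, length(rows)))
      sheets$response[pick] <- sample.int(10, length(pick), replace = TRUE)
    }
    sheets
  })
}
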