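#' Cosine similarity between pattern vectors
#'
#' The agreement between a calculated pattern vector and an expert-rated
#' one is measured by the cosine of the angle between them:
#' `dot(v1, v2) / (||v1|| * ||v2||)`. For non-negative vectors the value
#' lies in \[0, 1\]; 1 means identical direction, 0 means no shared
#' component.
#'
#' @param v1,v2 Numeric vectors of equal length with positive norm.
#' @return Cosine similarity at full precision.
#' @examples
#' cosine_similarity(c(0.073, 0.605, 0.322), c(0.469, 0.344, 0.188))
#' @export
cosine_similarity <- function(v1, v2) {
  v1 <- as.numeric(v1)
  v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) {
    abort("vectors must have equal length", class = "mfp_domain_error")
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort("cosine similarity is undefined for zero-norm vectors",
          class = "mfp_domain_error")
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Accept or reject a profile by similarity threshold
#'
#' A calculated profile is accepted when its similarity to the expert
#' rating reaches the threshold; the boundary is inclusive
#' (`similarity >= threshold`). The default threshold is 0.8.
#'
#' @param similarity Numeric similarity values in \[0, 1\].
#' @param threshold Acceptance threshold, default `0.8`.
#' @return Logical vector.
#' @export
similarity_verdict <- function(similarity, threshold = 0.8) {
  similarity >= threshold
}

#' Batch similarity report
#'
#' Compares calculated and expert pattern vectors pairwise, applying the
#' acceptance threshold to each. Expert ratings may be given either as
#' normalized proportions or as raw non-negative scores (e.g. integer
#' expert marks per pattern); cosine similarity is scale-invariant so
#' both give the same result.
#'
#' @param pairs Tibble with columns `respondent_id`, `calc_adaptive`,
#'   `calc_reactive`, `calc_creative`, `exp_adaptive`, `exp_reactive`,
#'   `exp_creative`.
#' @param threshold Acceptance threshold, default `0.8`.
#' @return A tibble of class `mfp_similarity_report` with the input
#'   columns plus `similarity` (full precision) and `accepted`; rows in
#'   input order. Summary statistics are available via [glance()].
#' @export
similarity_report <- function(pairs, threshold = 0.8) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    abort("at least one vector pair is required", class = "mfp_domain_error")
  }
  calc <- as.matrix(pairs[, paste0("calc_", PATTERNS)])
  expv <- as.matrix(pairs[, paste0("exp_", PATTERNS)])
  sim <- vapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(cosine_similarity(calc[i, ], expv[i, ]),
             mfp_domain_error = function(e) {
               abort(paste0("respondent '", pairs$respondent_id[[i]], "': ",
                            conditionMessage(e)),
                     class = "mfp_domain_error")
             })
  }, numeric(1))
  out <- dplyr::mutate(pairs, similarity = sim,
                       accepted = similarity_verdict(sim, threshold))
  attr(out, "threshold") <- threshold
  class(out) <- c("mfp_similarity_report", class(out))
  out
}

#' @describeIn similarity_report One-row summary: pairs compared, number
#'   and share accepted, mean similarity, threshold used.
#' @param x An `mfp_similarity_report`.
#' @param ... Unused.
#' @method glance mfp_similarity_report
#' @export
glance.mfp_similarity_report <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_accepted = sum(x$accepted),
    prop_accepted = mean(x$accepted),
    mean_similarity = mean(x$similarity),
    threshold = attr(x, "threshold")
  )
}

#' Count per-question disagreements against an expert rating
#'
#' Flags the questions on which a respondent's answer points away from
#' the expert's overall impression. Under the default `"dominant"`
#' policy a question disagrees when the dominant pattern of its fuzzy
#' triple differs from the dominant pattern of the expert vector;
#' questions whose triple is all-zero are skipped (they carry no
#' pattern signal). `policy = "none"` disables the count and returns
#' `NA`.
#'
#' The criterion is a modelling choice, not an estimate: expert workflows
#' may define disagreement differently, so the policy is pluggable.
#'
#' @param sheet Single-respondent tibble with `metric_id` and `response`
#'   columns (a `respondent_id` column is allowed and ignored).
#' @param catalog An `mfp_catalog`.
#' @param v_expert Expert pattern vector (three non-negative components).
#' @param policy `"dominant"` (default) or `"none"`.
#' @return Non-negative integer count, or `NA_integer_` when
#'   `policy = "none"`.
#' @export
count_disagreements <- function(sheet, catalog, v_expert,
                                policy = "dominant") {
  if (!policy %in% c("dominant", "none")) {
    abort(paste0("unknown disagreement policy '", policy, "'"),
          class = "mfp_config_error")
  }
  if (policy == "none") return(NA_integer_)
  sheet <- as_tibble(sheet)
  if (!"respondent_id" %in% names(sheet)) {
    sheet$respondent_id <- "respondent"
  }
  fuzzy <- fuzzify_sheets(sheet, catalog)
  expert_dom <- as.character(dominant_pattern(v_expert))
  per_question <- apply(as.matrix(fuzzy[, PATTERNS]), 1, function(tr) {
    if (sum(tr) == 0) return(NA_character_)
    as.character(dominant_pattern(tr))
  })
  sum(per_question != expert_dom, na.rm = TRUE)
}
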