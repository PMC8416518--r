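test_that("cosine similarity matches published anchor values", {
  # the published vectors are printed at 3 decimals, so recomputing the
  # similarity from them can shift the third decimal by one unit
  expect_lte(abs(cosine_similarity(c(0.073, 0.605, 0.322),
                                   c(0.469, 0.344, 0.188)) - 0.718), 0.002)
  expect_lte(abs(cosine_similarity(c(0.000, 0.000, 1.000),
                                   c(0.467, 0.400, 0.133)) - 0.212), 0.002)
  expect_equal(cosine_similarity(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1.0)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0.0)
})

test_that("cosine similarity is symmetric, scale-invariant and bounded", {
  set.seed(77)
  for (i in 1:1000) {
    a <- runif(3)
    b <- runif(3)
    s <- cosine_similarity(a, b)
    expect_identical(s, cosine_similarity(b, a))
    expect_true(s >= 0 && s <= 1 + 1e-12)
    expect_equal(cosine_similarity(a * 7.3, b), s, tolerance = 1e-12)
    expect_equal(s, oracle_cosine(a, b), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(c(0, 0, 0), c(1, 0, 0)),
               class = "mfp_domain_error")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)),
               class = "mfp_domain_error")
})

test_that("the acceptance verdict is inclusive at the threshold", {
  expect_true(similarity_verdict(0.803))
  expect_true(similarity_verdict(0.800))
  expect_false(similarity_verdict(0.794))
  expect_true(similarity_verdict(0.5, threshold = 0.5))
})

test_that("batch report reproduces the published clinical comparison", {
  pairs <- clinical_validation_pairs()
  rep <- similarity_report(pairs, threshold = 0.8)
  expect_equal(nrow(rep), 34)
  # printed similarities were rounded to 3 decimals; stay within the
  # rounding slack of the printed vectors
  expect_true(all(abs(round(rep$similarity, 3) - pairs$similarity) <= 0.002))
  # count of accepted profiles at the 0.8 threshold, from the printed column
  expect_equal(sum(pairs$similarity >= 0.8), 10)
  expect_equal(glance(rep)$n_accepted, 10)
  expect_equal(rep$accepted, pairs$similarity >= 0.8)
})

test_that("single identical pair gives a unit-similarity summary", {
  pairs <- tibble::tibble(respondent_id = "a",
                          calc_adaptive = 0.3, calc_reactive = 0.3,
                          calc_creative = 0.4,
                          exp_adaptive = 0.3, exp_reactive = 0.3,
                          exp_creative = 0.4)
  g <- glance(similarity_report(pairs))
  expect_equal(g$mean_similarity, 1.0)
  expect_equal(g$n_accepted, 1L)
})

test_that("expert ratings given as raw integer scores work unchanged", {
  # 4,2,1 normalizes to 4/7, 2/7, 1/7; cosine is scale-invariant
  raw <- tibble::tibble(respondent_id = "a",
                        calc_adaptive = 0.352, calc_reactive = 0.267,
                        calc_creative = 0.381,
                        exp_adaptive = 4, exp_reactive = 2,
                        exp_creative = 1)
  norm <- raw
  norm[paste0("exp_", c("adaptive", "reactive", "creative"))] <-
    list(4 / 7, 2 / 7, 1 / 7)
  expect_equal(similarity_report(raw)$similarity,
               similarity_report(norm)$similarity)
})

test_that("zero-norm pairs are reported with the offending respondent", {
  pairs <- tibble::tibble(respondent_id = "bad",
                          calc_adaptive = 0, calc_reactive = 0,
                          calc_creative = 0,
                          exp_adaptive = 1, exp_reactive = 0,
                          exp_creative = 0)
  expect_error(similarity_report(pairs), regexp = "bad",
               class = "mfp_domain_error")
})

test_that("disagreement counting follows the dominant-pattern policy", {
  cat <- default_catalog()
  ids <- metrics_for_driver(cat, "debt_collection")$metric_id[1:7]
  ids <- setdiff(ids, "beliefs")[1:5]  # keep the hand-reasoning simple
  # response 6 is reactive-dominant under the defaults, response 2 adaptive
  sheet <- tibble::tibble(respondent_id = "p",
                          metric_id = c(ids, "anxiety", "learned_resilience"),
                          response = c(rep(6L, 5), 2L, 2L))
  v_expert <- c(0.2, 0.6, 0.2)  # reactive-dominant expert impression
  expect_equal(count_disagreements(sheet, cat, v_expert), 2)
  # perfectly agreeing sheet
  all6 <- tibble::tibble(respondent_id = "p",
                         metric_id = c(ids, "anxiety", "learned_resilience"),
                         response = 6L)
  expect_equal(count_disagreements(all6, cat, v_expert), 0)
  expect_identical(count_disagreements(sheet, cat, v_expert,
                                       policy = "none"), NA_integer_)
  expect_error(count_disagreements(sheet, cat, v_expert, policy = "huh"),
               class = "mfp_config_error")
})

test_that("more injected corruption lowers mean similarity to expert ratings", {
  cat <- default_catalog()
  co <- simulate_cohort(cat, "debt_collection", n = 150, seed = 515)
  mean_sim <- function(q) {
    sheets <- corrupt_responses(co$sheets, q, seed = 900 + q)
    prof <- profile_respondents(sheets, cat, degenerate = "uniform")
    merged <- dplyr::inner_join(prof, co$expert_vectors,
                                by = "respondent_id",
                                suffix = c("_c", "_e"))
    mean(vapply(seq_len(nrow(merged)), function(i) {
      cosine_similarity(
        c(merged$adaptive_c[i], merged$reactive_c[i], merged$creative_c[i]),
        c(merged$adaptive_e[i], merged$reactive_e[i], merged$creative_e[i]))
    }, numeric(1)))
  }
  sims <- vapply(c(0, 3, 6), mean_sim, numeric(1))
  expect_true(sims[2] < sims[1])
  expect_true(sims[3] < sims[2])
})
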