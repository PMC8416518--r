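test_that("cohort generation is fully reproducible from its seed", {
  cat <- default_catalog()
  a <- simulate_cohort(cat, "debt_collection", n = 50, seed = 7)
  b <- simulate_cohort(cat, "debt_collection", n = 50, seed = 7)
  expect_identical(a$sheets, b$sheets)
  expect_identical(a$true_vectors, b$true_vectors)
  expect_identical(a$expert_vectors, b$expert_vectors)
  expect_identical(a$decisions, b$decisions)
  c <- simulate_cohort(cat, "debt_collection", n = 50, seed = 8)
  expect_false(identical(a$sheets$response, c$sheets$response))
})

test_that("generated responses are valid questionnaire answers", {
  cat <- default_catalog()
  gen <- generate_responses(cat, "debt_collection", n = 40, seed = 3)
  expected <- metrics_for_driver(cat, "debt_collection")
  for (id in unique(gen$sheets$respondent_id)) {
    sheet <- gen$sheets[gen$sheets$respondent_id == id, ]
    expect_true(validate_responses(sheet, expected)$ok)
  }
  # every true vector is a proper composition
  v <- as.matrix(gen$true_vectors[, c("adaptive", "reactive", "creative")])
  expect_true(all(abs(rowSums(v) - 1) < 1e-9))
  expect_true(all(v >= 0))
})

test_that("a sharply concentrated archetype dominates its pattern", {
  cat <- default_catalog()
  arch <- list(archetype("sharp", c(1, 98, 1), response_noise_sd = 0))
  gen <- generate_responses(cat, "debt_collection", n = 1000, seed = 12,
                            archetypes = arch)
  r <- gen$true_vectors$reactive
  # Beta-tail oracle: P(reactive <= 0.9) ~ 3.5e-4, so nearly every draw
  # exceeds 0.9 and the mean sits near the concentration ratio 0.98
  expect_gt(mean(r), 0.97)
  expect_gt(mean(r > 0.9), 0.99)
})

test_that("expert ratings reproduce representable vectors exactly at zero noise", {
  v <- tibble::tibble(adaptive = 0.4, reactive = 0.4, creative = 0.2)
  out <- generate_expert_ratings(v, integer_scale_max = 10, noise_sd = 0,
                                 seed = 1)
  expect_equal(unlist(out, use.names = FALSE), c(0.4, 0.4, 0.2))
})

test_that("expert ratings stay close to the truth at low noise", {
  set.seed(2)
  g <- matrix(rgamma(500 * 3, shape = 2), ncol = 3)
  v <- tibble::as_tibble(as.data.frame(g / rowSums(g)))
  names(v) <- c("adaptive", "reactive", "creative")
  out <- generate_expert_ratings(v, noise_sd = 0.05, seed = 9)
  expect_true(all(abs(rowSums(as.matrix(out)) - 1) < 1e-9))
  sims <- vapply(seq_len(nrow(v)), function(i) {
    cosine_similarity(as.numeric(v[i, ]), as.numeric(out[i, ]))
  }, numeric(1))
  expect_gt(mean(sims), 0.95)
})

test_that("decision labels are a deterministic rule plus controlled noise", {
  set.seed(5)
  g <- matrix(rgamma(2000 * 3, shape = 1), ncol = 3)
  v <- as.data.frame(g / rowSums(g))
  names(v) <- c("adaptive", "reactive", "creative")
  var4 <- decision_variable("v4", c("a", "b", "c", "d"))

  clean1 <- generate_decisions(v, var4, label_noise = 0, seed = 1)
  clean2 <- generate_decisions(v, var4, label_noise = 0, seed = 999)
  expect_identical(clean1, clean2)  # no randomness at zero noise
  # equal-mass bins over 2000 rows
  expect_equal(unname(table(clean1))[1], 500L)

  noisy <- generate_decisions(v, var4, label_noise = 0.2, seed = 42)
  flip_frac <- mean(noisy != clean1)
  # 3-sigma binomial band around p = 0.2 at n = 2000: +/- 0.027
  expect_true(abs(flip_frac - 0.2) <= 0.03)

  # with two classes, full noise flips every label
  var2 <- decision_variable("v2", c("yes", "no"))
  clean_b <- generate_decisions(v, var2, label_noise = 0, seed = 1)
  flipped <- generate_decisions(v, var2, label_noise = 1, seed = 3)
  expect_true(all(flipped != clean_b))
})

test_that("labels track the pattern gradient through the linear score", {
  v <- tibble::tibble(adaptive = c(0.9, 0.1, 0.1),
                      reactive = c(0.05, 0.8, 0.1),
                      creative = c(0.05, 0.1, 0.8))
  var <- decision_variable("v3", c("low", "mid", "high"))
  lab <- generate_decisions(v, var, label_noise = 0, seed = 1)
  # score = 0.5*reactive + creative orders the three rows
  expect_equal(lab, c("low", "mid", "high"))
})

test_that("generator misconfiguration is rejected", {
  cat <- default_catalog()
  expect_error(generate_responses(cat, "debt_collection", n = 5, seed = 1,
                                  archetypes = list()),
               class = "mfp_config_error")
  expect_error(generate_responses(cat, "debt_collection", n = 5, seed = 1,
                                  mix = c(0.5, 0.2)),
               class = "mfp_config_error")
  expect_error(archetype("x", c(1, 0, 1)), class = "mfp_config_error")
  expect_error(generate_decisions(tibble::tibble(adaptive = 1, reactive = 0,
                                                 creative = 0),
                                  decision_variable("v", c("a", "b")),
                                  label_noise = 2),
               class = "mfp_config_error")
})
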