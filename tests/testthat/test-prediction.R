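test_that("largest-remainder apportionment matches its oracle", {
  fr <- c(train = 0.70, test = 0.18, validation = 0.12)
  expect_equal(unname(split_sizes(100, fr)), c(70L, 18L, 12L))
  expect_equal(unname(split_sizes(1204, fr)), c(843L, 217L, 144L))
  expect_equal(unname(split_sizes(10, fr)), c(7L, 2L, 1L))
  set.seed(33)
  for (n in sample(3:5000, 40)) {
    expect_equal(unname(split_sizes(n, fr)), oracle_apportion(n, fr))
    expect_equal(sum(split_sizes(n, fr)), n)
  }
  expect_error(split_sizes(10, c(0.5, 0.4)), class = "mfp_config_error")
})

test_that("dataset splits are disjoint, exhaustive and seed-deterministic", {
  df <- tibble::tibble(respondent_id = sprintf("r%03d", 1:100),
                       x = rnorm(100), decision = sample(c("A", "B"), 100,
                                                         replace = TRUE))
  s1 <- split_dataset(df, seed = 5)
  s2 <- split_dataset(df, seed = 5)
  s3 <- split_dataset(df, seed = 6)
  expect_equal(vapply(s1, nrow, integer(1)),
               c(train = 70L, test = 18L, validation = 12L))
  expect_identical(s1, s2)
  expect_false(identical(s1$train$respondent_id, s3$train$respondent_id))
  expect_equal(vapply(s3, nrow, integer(1)), vapply(s1, nrow, integer(1)))
  all_ids <- sort(unname(unlist(lapply(s1, function(d) d$respondent_id))))
  expect_equal(all_ids, sort(df$respondent_id))
})

test_that("nearest-neighbour voting follows the declared tie-breaks", {
  train <- tibble::tibble(x = c(0, 1, 2), decision = c("A", "A", "B"))
  m1 <- train_knn(train, k = 1)
  expect_equal(predict(m1, tibble::tibble(x = 2)), "B")
  m3 <- train_knn(train, k = 3)
  expect_equal(predict(m3, tibble::tibble(x = 5)), "A")  # majority of A,A,B
  # vote tie: label of the strictly nearest point wins
  tie <- train_knn(tibble::tibble(x = c(0, 2), decision = c("A", "B")),
                   k = 2)
  expect_equal(predict(tie, tibble::tibble(x = 0.9)), "A")
  expect_equal(predict(tie, tibble::tibble(x = 1.1)), "B")
  # equidistant contenders rank by training order
  eq <- train_knn(tibble::tibble(x = c(1, -1), decision = c("A", "B")),
                  k = 2)
  expect_equal(predict(eq, tibble::tibble(x = 0)), "A")
  expect_error(train_knn(train, k = 4), class = "mfp_config_error")
  expect_error(train_knn(train[0, ], k = 1), class = "mfp_config_error")
})

test_that("our nearest-neighbour agrees with an established implementation", {
  skip_if_not_installed("class")
  set.seed(99)
  train <- tibble::tibble(a = rnorm(60), b = rnorm(60),
                          decision = sample(c("x", "y", "z"), 60,
                                            replace = TRUE))
  query <- tibble::tibble(a = rnorm(25), b = rnorm(25))
  ours <- predict(train_knn(train, k = 1), query)
  ref <- as.character(class::knn(train[, c("a", "b")],
                                 query, cl = train$decision, k = 1))
  expect_equal(ours, ref)
})

test_that("random baseline and gain reproduce the published arithmetic", {
  expect_equal(random_baseline(2), 50)
  expect_equal(round(random_baseline(15), 2), 6.67)
  expect_equal(round(random_baseline(6), 2), 16.67)
  expect_equal(random_baseline(5), 20)
  expect_equal(compute_gain(60.14, 50.00), 1.2028)
  expect_equal(round(compute_gain(46.74, 6.67), 4), 7.0075)
  expect_equal(compute_gain(50, 50), 1.0)
  expect_error(compute_gain(10, 0), class = "mfp_domain_error")
  # gain x random = success, by construction
  expect_equal(compute_gain(56.06, 16.67) * 16.67, 56.06)
})

test_that("model evaluation matches a hand-computed confusion matrix", {
  # confusion: A->A twice, A->B once, B->B once, B->A once
  train <- tibble::tibble(x = c(0, 10), decision = c("A", "B"))
  model <- train_knn(train, k = 1)
  validation <- tibble::tibble(x = c(0, 1, 9, 10, 2),
                               decision = c("A", "A", "A", "B", "B"))
  # predictions: A A B B A
  var <- decision_variable("toy", c("A", "B"))
  ev <- evaluate_model(model, validation, var)
  expect_equal(ev$accuracy, 60)
  expect_equal(ev$success_rate, 60)
  expect_equal(round(ev$macro_precision, 2), 58.33)
  expect_equal(round(ev$macro_recall, 2), 58.33)
  expect_equal(ev$gain, 60 / 50)
  expect_error(
    evaluate_model(model,
                   tibble::tibble(x = 1, decision = "C"), var),
    class = "mfp_data_error")
})

test_that("all-correct predictions give the ceiling metrics", {
  train <- tibble::tibble(x = c(0, 5, 10), decision = c("A", "B", "C"))
  model <- train_knn(train, k = 1)
  var <- decision_variable("toy3", c("A", "B", "C"))
  ev <- evaluate_model(model, train, var)
  expect_equal(ev$success_rate, 100)
  expect_equal(ev$gain, 3)
  expect_equal(ev$macro_precision, 100)
  expect_equal(ev$macro_recall, 100)
})

test_that("a constant classifier on a balanced multiclass set sits at chance", {
  set.seed(4)
  # all training labels equal: prediction is constant
  train <- tibble::tibble(x = rnorm(20), decision = "A")
  model <- train_knn(train, k = 5)
  validation <- tibble::tibble(x = rnorm(400),
                               decision = rep(c("A", "B", "C", "D"), 100))
  ev <- evaluate_model(model, validation,
                       decision_variable("v", c("A", "B", "C", "D")))
  expect_equal(ev$success_rate, 25)   # exactly balanced truth
  expect_equal(ev$gain, 1)
})

test_that("feedback merging ratifies, rectifies, skips pending and is idempotent", {
  training <- tibble::tibble(respondent_id = c("t1", "t2"),
                             x = c(1, 2), decision = c("A", "B"))
  repo <- tibble::tibble(
    respondent_id = c("n1", "n2", "n3"),
    x = c(3, 4, 5),
    predicted_decision = c("A", "A", "B"),
    validation_status = c("ratified", "rectified", "pending"),
    validated_decision = c(NA, "B", NA)
  )
  merged <- feedback_cycle(repo, training)
  expect_equal(nrow(merged), 4)
  expect_equal(merged$decision[merged$respondent_id == "n1"], "A")
  expect_equal(merged$decision[merged$respondent_id == "n2"], "B")
  expect_false("n3" %in% merged$respondent_id)
  # idempotent per respondent
  expect_equal(feedback_cycle(repo, merged), merged)
  # conflicting duplicate entries are rejected
  bad <- dplyr::bind_rows(repo[1, ], dplyr::mutate(repo[1, ],
                                                   predicted_decision = "B"))
  expect_error(feedback_cycle(bad, training),
               class = "mfp_consistency_error")
  # rectified must differ from the prediction
  bad2 <- dplyr::mutate(repo[2, ], validated_decision = "A")
  expect_error(feedback_cycle(bad2, training),
               class = "mfp_consistency_error")
})
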