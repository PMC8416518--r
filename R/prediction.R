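#' Largest-remainder apportionment of split sizes
#'
#' Computes integer subset sizes for a train/test/validation split by
#' the largest-remainder rule: each fraction gets its floor, and the
#' remaining slots go to the largest fractional remainders (ties by
#' subset order). The sizes are exact where the fractions divide `n`.
#'
#' @param n Number of observations.
#' @param fractions Positive fractions summing to 1; default
#'   `c(train = 0.70, test = 0.18, validation = 0.12)`.
#' @return Named integer vector of sizes summing to `n`.
#' @examples
#' split_sizes(1204)  # 843, 217, 144
#' @export
split_sizes <- function(n, fractions = c(train = 0.70, test = 0.18,
                                         validation = 0.12)) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("split fractions must be positive and sum to 1",
          class = "mfp_config_error")
  }
  quota <- n * fractions
  sizes <- floor(quota)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  setNames(as.integer(sizes), names(fractions))
}

#' Split a labelled dataset into train/test/validation
#'
#' Shuffles rows with a seeded permutation and partitions them into
#' disjoint, exhaustive subsets whose sizes follow the
#' largest-remainder apportionment of the fractions. Identical seeds
#' give identical partitions.
#'
#' @param profiles Data frame of labelled profiles (one row per
#'   respondent).
#' @param fractions See [split_sizes()].
#' @param seed Integer seed driving the shuffle.
#' @return Named list of tibbles `train`, `test`, `validation`.
#' @export
split_dataset <- function(profiles, fractions = c(train = 0.70, test = 0.18,
                                                  validation = 0.12),
                          seed = 1L) {
  profiles <- as_tibble(profiles)
  n <- nrow(profiles)
  if (n < 3) {
    abort("need at least 3 profiles to split", class = "mfp_config_error")
  }
  sizes <- split_sizes(n, fractions)
  perm <- with_local_seed(seed, sample.int(n))
  bounds <- cumsum(sizes)
  starts <- c(1, head(bounds, -1) + 1)
  out <- purrr::map2(starts, bounds, function(s, e) {
    profiles[perm[seq(s, e)], , drop = FALSE]
  })
  setNames(out, names(sizes))
}

#' Train a nearest-neighbour decision model
#'
#' Stores the training features and labels; prediction is by majority
#' vote among the `k` nearest training rows under the chosen distance.
#' A vote tie is broken by the label of the single nearest neighbour
#' (equidistant neighbours rank by training order, which makes
#' prediction deterministic).
#'
#' @param train Data frame of labelled profiles.
#' @param k Number of neighbours, default 5.
#' @param distance `"euclidean"` (default) or `"manhattan"`.
#' @param feature_cols Character vector of feature column names; default
#'   every numeric column except `label_col`.
#' @param label_col Name of the decision column, default `"decision"`.
#' @return An object of class `mfp_knn`.
#' @export
train_knn <- function(train, k = 5L, distance = c("euclidean", "manhattan"),
                      feature_cols = NULL, label_col = "decision") {
  distance <- match.arg(distance)
  train <- as_tibble(train)
  if (nrow(train) == 0) {
    abort("training set is empty", class = "mfp_config_error")
  }
  if (k < 1 || k > nrow(train)) {
    abort(paste0("k must lie in 1..", nrow(train)),
          class = "mfp_config_error")
  }
  if (is.null(feature_cols)) {
    numeric_cols <- names(train)[vapply(train, is.numeric, logical(1))]
    feature_cols <- setdiff(numeric_cols, label_col)
  }
  structure(
    list(features = as.matrix(train[, feature_cols, drop = FALSE]),
         labels = as.character(train[[label_col]]),
         k = as.integer(k), distance = distance,
         feature_cols = feature_cols, label_col = label_col),
    class = "mfp_knn"
  )
}

#' @export
print.mfp_knn <- function(x, ...) {
  cat("<mfp_knn> k = ", x$k, ", ", x$distance, " distance, ",
      nrow(x$features), " training rows, ",
      length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' Predict decisions with a nearest-neighbour model
#'
#' @param object An `mfp_knn` model.
#' @param newdata Data frame containing the model's feature columns (or
#'   a bare numeric matrix in feature order).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.mfp_knn <- function(object, newdata, ...) {
  q <- if (is.matrix(newdata)) newdata else
    as.matrix(as_tibble(newdata)[, object$feature_cols, drop = FALSE])
  tr <- object$features
  vapply(seq_len(nrow(q)), function(i) {
    d <- if (object$distance == "euclidean") {
      sqrt(colSums((t(tr) - q[i, ])^2))
    } else {
      colSums(abs(t(tr) - q[i, ]))
    }
    nn <- order(d)[seq_len(object$k)]  # stable: equidistant by training order
    votes <- table(object$labels[nn])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1) winners else object$labels[nn[[1]]]
  }, character(1))
}

#' @describeIn train_knn Tidy view of the stored training set (one row
#'   per training instance with its label).
#' @param x An `mfp_knn` model.
#' @param ... Unused.
#' @method tidy mfp_knn
#' @export
tidy.mfp_knn <- function(x, ...) {
  dplyr::bind_cols(as_tibble(x$features),
                   tibble(!!x$label_col := x$labels))
}

#' @describeIn train_knn One-row model summary (k, distance, sizes).
#' @method glance mfp_knn
#' @export
glance.mfp_knn <- function(x, ...) {
  tibble(k = x$k, distance = x$distance, n_train = nrow(x$features),
         n_features = ncol(x$features), n_classes = length(unique(x$labels)))
}

#' Declare a decision variable
#'
#' A decision variable is the categorical quantity being predicted, with
#' its closed enumeration of classes (e.g. the discount tier chosen in a
#' debt negotiation).
#'
#' @param name Variable name.
#' @param classes Character (or coercible) vector of at least two
#'   distinct class labels.
#' @return An object of class `mfp_decision_variable`.
#' @export
decision_variable <- function(name, classes) {
  classes <- as.character(classes)
  if (length(classes) < 2 || anyDuplicated(classes)) {
    abort("a decision variable needs at least two distinct classes",
          class = "mfp_config_error")
  }
  structure(list(name = name, classes = classes,
                 n_classes = length(classes)),
            class = "mfp_decision_variable")
}

#' @export
print.mfp_decision_variable <- function(x, ...) {
  cat("<mfp_decision_variable> ", x$name, ": ", x$n_classes, " classes (",
      paste(x$classes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Random-choice baseline success rate
#'
#' The expected percentage of correct predictions under uniform random
#' guessing over the class enumeration: `100 / n_classes`.
#'
#' @param variable An `mfp_decision_variable`, or an integer class count.
#' @return Percent in (0, 100\].
#' @examples
#' random_baseline(2)   # 50
#' random_baseline(15)  # 6.666...
#' @export
random_baseline <- function(variable) {
  k <- if (inherits(variable, "mfp_decision_variable")) variable$n_classes
       else as.integer(variable)
  if (is.na(k) || k < 1) {
    abort("number of classes must be a positive integer",
          class = "mfp_domain_error")
  }
  100 / k
}

#' Gain of a model over random choice
#'
#' The ratio of the model's success rate to the random baseline; a gain
#' of 1 means no better than chance.
#'
#' @param success_rate Model success rate, percent.
#' @param random_rate Random baseline, percent; must be positive.
#' @return Gain ratio.
#' @examples
#' compute_gain(60.14, 50.00)  # 1.2028
#' @export
compute_gain <- function(success_rate, random_rate) {
  if (any(random_rate <= 0)) {
    abort("random rate must be positive", class = "mfp_domain_error")
  }
  success_rate / random_rate
}

#' Evaluate a decision model on a validation set
#'
#' Computes the success rate (percent correct), its gain over the random
#' baseline, and macro-averaged precision and recall. Macro averages are
#' unweighted means over the labels present in the validation truth; a
#' label never predicted contributes precision 0.
#'
#' @param model An `mfp_knn` model.
#' @param validation Data frame of labelled profiles (same columns as
#'   training).
#' @param variable The `mfp_decision_variable` being predicted; the
#'   validation labels must come from its enumeration.
#' @return One-row tibble of class `mfp_evaluation` with columns
#'   `decision_variable`, `n_classes`, `random_rate`, `success_rate`,
#'   `gain`, `accuracy`, `macro_precision`, `macro_recall`,
#'   `n_validation`.
#' @export
evaluate_model <- function(model, validation, variable) {
  stopifnot(inherits(model, "mfp_knn"),
            inherits(variable, "mfp_decision_variable"))
  validation <- as_tibble(validation)
  if (nrow(validation) == 0) {
    abort("validation set is empty", class = "mfp_config_error")
  }
  truth <- as.character(validation[[model$label_col]])
  bad <- setdiff(unique(truth), variable$classes)
  if (length(bad) > 0) {
    abort(paste0("validation labels outside the enumeration of '",
                 variable$name, "': ", paste(bad, collapse = ", ")),
          class = "mfp_data_error")
  }
  pred <- predict(model, validation)
  metrics <- classification_metrics(truth, pred)
  random_rate <- random_baseline(variable)
  success_rate <- metrics$accuracy
  out <- tibble(
    decision_variable = variable$name,
    n_classes = variable$n_classes,
    random_rate = random_rate,
    success_rate = success_rate,
    gain = compute_gain(success_rate, random_rate),
    accuracy = metrics$accuracy,
    macro_precision = metrics$macro_precision,
    macro_recall = metrics$macro_recall,
    n_validation = nrow(validation)
  )
  class(out) <- c("mfp_evaluation", class(out))
  out
}

# confusion-matrix metrics in percent; macro means are over the labels
# present in the truth, with precision 0 for labels never predicted
classification_metrics <- function(truth, pred) {
  labels <- sort(unique(truth))
  accuracy <- 100 * mean(truth == pred)
  precision <- vapply(labels, function(l) {
    predicted <- pred == l
    if (!any(predicted)) return(0)
    100 * sum(predicted & truth == l) / sum(predicted)
  }, numeric(1))
  recall <- vapply(labels, function(l) {
    actual <- truth == l
    100 * sum(actual & pred == l) / sum(actual)
  }, numeric(1))
  list(accuracy = accuracy,
       macro_precision = mean(precision),
       macro_recall = mean(recall))
}

#' Merge validated predictions back into the training set
#'
#' Implements the human-in-the-loop feedback step: predictions reviewed
#' by validators are appended to the training sample, using the
#' validated decision for rectified records and the predicted decision
#' for ratified ones. Pending records are skipped. Respondents already
#' present in the training set are not appended again, so the cycle is
#' idempotent.
#'
#' @param repository Tibble with columns `respondent_id`, the feature
#'   columns, `predicted_decision`, `validation_status` (`"pending"`,
#'   `"ratified"` or `"rectified"`) and `validated_decision` (required
#'   for rectified records, and must differ from the prediction).
#' @param training Tibble of labelled profiles with a `respondent_id`
#'   column and a `decision` column.
#' @return The augmented training tibble.
#' @export
feedback_cycle <- function(repository, training) {
  repository <- as_tibble(repository)
  training <- as_tibble(training)
  dup <- repository$respondent_id[duplicated(repository$respondent_id)]
  if (length(dup) > 0) {
    conflicting <- unique(dup[vapply(dup, function(id) {
      rows <- repository[repository$respondent_id == id, ]
      lab <- ifelse(rows$validation_status == "rectified",
                    rows$validated_decision, rows$predicted_decision)
      length(unique(lab)) > 1
    }, logical(1))])
    if (length(conflicting) > 0) {
      abort(paste0("conflicting labels in repository for respondent(s): ",
                   paste(conflicting, collapse = ", ")),
            class = "mfp_consistency_error")
    }
    repository <- repository[!duplicated(repository$respondent_id), ]
  }
  validated <- repository[repository$validation_status %in%
                            c("ratified", "rectified"), ]
  bad <- validated$validation_status == "rectified" &
    (is.na(validated$validated_decision) |
       validated$validated_decision == validated$predicted_decision)
  if (any(bad)) {
    abort("rectified records must carry a validated_decision that differs from the prediction",
          class = "mfp_consistency_error")
  }
  new_rows <- validated[!validated$respondent_id %in% training$respondent_id, ]
  if (nrow(new_rows) == 0) return(training)
  new_rows$decision <- ifelse(new_rows$validation_status == "rectified",
                              new_rows$validated_decision,
                              new_rows$predicted_decision)
  keep <- intersect(names(training), names(new_rows))
  dplyr::bind_rows(training, new_rows[, keep])
}

# run code under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
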