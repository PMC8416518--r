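# Shared fixtures and independent oracles for the test suite.

# tiny catalog: two plain metrics, one reverse-keyed, one driver
tiny_catalog <- function() {
  metrics <- tibble::tibble(
    metric_id = c("calm", "grit", "tradition"),
    name = c("Calm", "Grit", "Tradition"),
    category = c("primary", "primary", "circumstantial"),
    question_text = c("Q1", "Q2", "Q3"),
    anchor_left = c("No", "No", "Yes"),
    anchor_center = c("Sometimes", "Sometimes", "Sometimes"),
    anchor_right = c("Yes", "Yes", "No"),
    reversed = c(FALSE, FALSE, TRUE)
  )
  drivers <- tibble::tibble(
    driver_id = "toy",
    name = "Toy context",
    circumstantial = list("tradition"),
    primary = list(c("calm", "grit"))
  )
  new_catalog(metrics, drivers)
}

# from-scratch cosine oracle, kept deliberately naive
oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# brute-force normalization oracle for profile aggregation
oracle_aggregate <- function(rows) {
  sums <- c(0, 0, 0)
  for (i in seq_len(nrow(rows))) {
    sums <- sums + as.numeric(rows[i, ])
  }
  sums / sum(sums)
}

# largest-remainder oracle, written independently of split_sizes()
oracle_apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- exact - base
  leftover <- n - sum(base)
  while (leftover > 0) {
    i <- which.max(rem)
    base[i] <- base[i] + 1
    rem[i] <- -1
    leftover <- leftover - 1
  }
  as.integer(base)
}

default_set <- function() default_fuzzifiers()$default

debt_metric_ids <- function() {
  metrics_for_driver(default_catalog(), "debt_collection")$metric_id
}
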