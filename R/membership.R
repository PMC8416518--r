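#' Fuzzy membership functions on the 1-10 response scale
#'
#' A membership (pertinence) function maps a questionnaire response on
#' the 1-10 scale to a degree of fit in \[0, 1\] with one behavioural
#' pattern. Two shapes are supported: `triangular` with breakpoints
#' `(a, b, c)` (degree 0 at and outside the feet `a` and `c`, 1 at the
#' apex `b`) and `trapezoidal` with breakpoints `(a, b, c, d)` (degree 1
#' on the plateau `[b, c]`). Between breakpoints the degree is linear.
#' A zero-width edge (e.g. `b == c` in a triangle) makes a shoulder: the
#' degree stays 1 at that end of the support.
#'
#' @param breakpoints Numeric vector of length 3 (triangular) or 4
#'   (trapezoidal); non-decreasing, within \[1, 10\].
#' @return An object of class `mfp_membership`.
#' @examples
#' fn <- trapezoidal(3.5, 5.5, 7.5, 9.5)
#' evaluate_membership(fn, 6)    # 1, on the plateau
#' evaluate_membership(fn, 4.5)  # 0.5, halfway up the rising edge
#' @name membership
NULL

new_membership <- function(kind, breakpoints) {
  breakpoints <- as.numeric(breakpoints)
  n_expected <- if (kind == "triangular") 3L else 4L
  if (length(breakpoints) != n_expected) {
    abort(paste0(kind, " membership function needs ", n_expected,
                 " breakpoints"), class = "mfp_validation_error")
  }
  if (is.unsorted(breakpoints)) {
    abort("membership breakpoints must be non-decreasing",
          class = "mfp_validation_error")
  }
  if (breakpoints[1] < 1 || breakpoints[length(breakpoints)] > 10) {
    abort("membership breakpoints must lie within [1, 10]",
          class = "mfp_validation_error")
  }
  structure(list(kind = kind, breakpoints = breakpoints),
            class = "mfp_membership")
}

#' @rdname membership
#' @param a,b,c,d Breakpoints on the response scale.
#' @export
triangular <- function(a, b, c) new_membership("triangular", c(a, b, c))

#' @rdname membership
#' @export
trapezoidal <- function(a, b, c, d) new_membership("trapezoidal", c(a, b, c, d))

#' @export
print.mfp_membership <- function(x, ...) {
  cat("<mfp_membership> ", x$kind, "(",
      paste(format(x$breakpoints), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a membership function
#'
#' @param fn An `mfp_membership` created by [triangular()] or
#'   [trapezoidal()].
#' @param response Numeric vector of responses in \[1, 10\] (the
#'   questionnaire interface uses integers; evaluation accepts reals).
#' @return Numeric vector of degrees in \[0, 1\].
#' @export
evaluate_membership <- function(fn, response) {
  stopifnot(inherits(fn, "mfp_membership"))
  response <- as.numeric(response)
  if (any(is.na(response)) || any(response < 1) || any(response > 10)) {
    abort("response must lie within [1, 10]", class = "mfp_domain_error")
  }
  bp <- fn$breakpoints
  if (fn$kind == "triangular") {
    piecewise_degree(response, bp[1], bp[2], bp[2], bp[3])
  } else {
    piecewise_degree(response, bp[1], bp[2], bp[3], bp[4])
  }
}

# trapezoid core shared by both shapes (triangle = zero-width plateau);
# zero-width rising/falling edges become shoulders with degree 1
piecewise_degree <- function(x, a, b, c, d) {
  out <- numeric(length(x))
  plateau <- x >= b & x <= c
  out[plateau] <- 1
  rising <- x >= a & x < b
  if (b > a) out[rising] <- (x[rising] - a) / (b - a) else out[rising] <- 1
  falling <- x > c & x <= d
  if (d > c) out[falling] <- (d - x[falling]) / (d - c) else out[falling] <- 1
  pmin(1, pmax(0, out))
}

#' Default membership-function set
#'
#' One canonical set of three pertinence functions, applied to every
#' metric unless a per-metric override is configured:
#' adaptive = `triangular(1, 2.5, 5.5)`, reactive =
#' `trapezoidal(3.5, 5.5, 7.5, 9.5)`, creative = `triangular(6.5, 10, 10)`.
#' The reactive function is trapezoidal because reactive alignment
#' saturates over a band of responses rather than peaking at a single
#' value; the adaptive and creative functions anchor the low and high
#' ends of the scale. Breakpoints are configuration, not estimates: they
#' can be replaced wholesale via the `fuzzifiers:` section of a catalog
#' document.
#'
#' @return A named list with entry `default`, itself a list with one
#'   `mfp_membership` per pattern (`adaptive`, `reactive`, `creative`).
#' @export
default_fuzzifiers <- function() {
  list(default = list(
    adaptive = triangular(1, 2.5, 5.5),
    reactive = trapezoidal(3.5, 5.5, 7.5, 9.5),
    creative = triangular(6.5, 10, 10)
  ))
}

#' Look up the fuzzifier set for a metric
#'
#' @param catalog An `mfp_catalog`.
#' @param metric_id Metric identifier.
#' @return A list with one `mfp_membership` per pattern.
#' @export
fuzzifier_for <- function(catalog, metric_id) {
  stopifnot(inherits(catalog, "mfp_catalog"))
  catalog$fuzzifiers[[metric_id]] %||% catalog$fuzzifiers$default
}

parse_fuzzifier_config <- function(cfg) {
  parse_set <- function(set, where) {
    missing <- setdiff(PATTERNS, names(set))
    if (length(missing) > 0) {
      abort(paste0("fuzzifier set '", where, "' is missing patterns: ",
                   paste(missing, collapse = ", ")),
            class = "mfp_validation_error")
    }
    lapply(set[PATTERNS], function(fn) {
      new_membership(fn$kind, unlist(fn$breakpoints))
    })
  }
  out <- lapply(names(cfg), function(nm) parse_set(cfg[[nm]], nm))
  names(out) <- names(cfg)
  if (is.null(out$default)) {
    abort("fuzzifier config must define a 'default' set",
          class = "mfp_validation_error")
  }
  out
}

fuzzifier_config <- function(fuzzifiers) {
  lapply(fuzzifiers, function(set) {
    lapply(set, function(fn) {
      list(kind = fn$kind, breakpoints = as.list(fn$breakpoints))
    })
  })
}
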