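#' Resubmission distribution of manuscripts
#'
#' A manuscript that is rejected may be resubmitted (to another journal); the
#' model summarizes this by the distribution of the total number of times a
#' manuscript is submitted. `resubmission_distribution()` builds the
#' distribution from exact probabilities (probability of being submitted
#' exactly `i` times, for `i = 1..I`); `resubmission_from_cumulative()` builds
#' it from the cumulative form (probability of being submitted at least `i`
#' times). The same distribution is applied to manuscripts that are ultimately
#' published and to those that never are: the two could in principle differ,
#' but only their product with the (unknowable) count of unpublished
#' manuscripts is identified, so a single distribution keeps the model
#' identifiable.
#'
#' @param exact_probs Numeric vector; `exact_probs[i]` is the probability that
#'   a manuscript is submitted exactly `i` times. Must be non-negative and sum
#'   to 1 (inputs off by more than 1e-6 are rejected rather than silently
#'   renormalized).
#' @param cumulative Numeric vector; `cumulative[i]` is the probability that a
#'   manuscript is submitted at least `i` times. Must start at 1 and be
#'   non-increasing.
#'
#' @return An object of class `resubmission_distribution` with fields
#'   `exact`, `cumulative` and `max_submissions`.
#'
#' @examples
#' d <- resubmission_distribution(c(0.05, 0.10, 0.85))
#' d$cumulative                          # 1.00 0.95 0.85
#' expected_submissions_per_manuscript(d) # 5.45
#' @export
resubmission_distribution <- function(exact_probs) {
  exact <- check_probs(exact_probs, "resubmission distribution")
  cumulative <- rev(cumsum(rev(exact)))
  cumulative[[1L]] <- 1
  structure(
    list(exact = unname(exact),
         cumulative = unname(cumulative),
         max_submissions = length(exact)),
    class = "resubmission_distribution"
  )
}

#' @rdname resubmission_distribution
#' @export
resubmission_from_cumulative <- function(cumulative) {
  if (length(cumulative) == 0L || anyNA(cumulative)) {
    stop("cumulative probabilities must be non-empty and non-missing",
         call. = FALSE)
  }
  if (abs(cumulative[[1L]] - 1) > 1e-9) {
    stop("cumulative[1] must be 1 (every manuscript is submitted at least once)",
         call. = FALSE)
  }
  if (any(diff(cumulative) > 1e-12)) {
    stop("cumulative probabilities must be non-increasing", call. = FALSE)
  }
  exact <- c(-diff(cumulative), cumulative[[length(cumulative)]])
  resubmission_distribution(pmax(exact, 0))
}

#' @export
print.resubmission_distribution <- function(x, ...) {
  cat("Resubmission distribution: support 1..", x$max_submissions, "\n", sep = "")
  cat("  exact:      ", paste(format(x$exact, digits = 4), collapse = " "), "\n")
  cat("  cumulative: ", paste(format(x$cumulative, digits = 4), collapse = " "), "\n")
  cat("  inner-sum submissions per manuscript:",
      format(expected_submissions_per_manuscript(x), digits = 6), "\n")
  invisible(x)
}

#' Submissions per manuscript under the demand model
#'
#' The demand model counts, per manuscript, `sum_i i * R_i` where `R_i` is
#' the probability of at least `i` submissions: the i-th submission occasion
#' carries weight `i`. Equivalently, a manuscript submitted exactly `k` times
#' contributes `k(k+1)/2` submission units. (This is the model's accounting,
#' deliberately heavier than the plain expected submission count
#' `sum_i R_i`.)
#'
#' @param dist A [resubmission_distribution()].
#' @return A scalar, always at least 1.
#' @export
expected_submissions_per_manuscript <- function(dist) {
  stopifnot(inherits(dist, "resubmission_distribution"))
  sum(dist$cumulative * seq_len(dist$max_submissions))
}

#' Reviewer-effort distribution
#'
#' The proportion `P_j` of active reviewers who complete exactly `j` reviews
#' in a year (empirically heavy-tailed; on the Publons platform about 42% of
#' reviewers reported a single review in 2015). Counts absent from the input
#' mapping are allowed and treated as probability 0.
#'
#' @param probs Numeric vector of probabilities. If named, names are the
#'   review counts `j` (positive integers); if unnamed, element `i` is taken
#'   as `P_i`. Must be non-negative with total mass 1 within 1e-6.
#'
#' @return An object of class `effort_distribution` with fields `probs`
#'   (dense, index = review count), `max_reviews` and `mean_reviews`
#'   (`sum_j P_j * j`, the mean annual reviews per active reviewer).
#'
#' @examples
#' effort_distribution(c(`1` = 0.6, `2` = 0.4))$mean_reviews  # 1.4
#' @export
effort_distribution <- function(probs) {
  if (length(probs) == 0L) {
    stop("effort distribution: empty mapping", call. = FALSE)
  }
  if (is.null(names(probs))) {
    j <- seq_along(probs)
  } else {
    j <- suppressWarnings(as.integer(names(probs)))
    if (anyNA(j) || any(j < 1) || anyDuplicated(j) > 0L) {
      stop("effort distribution: names must be distinct positive integer review counts",
           call. = FALSE)
    }
  }
  dense <- numeric(max(j))
  dense[j] <- as.numeric(probs)
  dense <- check_probs(dense, "effort distribution")
  structure(
    list(probs = dense,
         max_reviews = length(dense),
         mean_reviews = sum(dense * seq_along(dense))),
    class = "effort_distribution"
  )
}

#' @export
print.effort_distribution <- function(x, ...) {
  cat("Reviewer-effort distribution: support 1..", x$max_reviews, "\n", sep = "")
  cat("  mean reviews per active reviewer:",
      format(x$mean_reviews, digits = 6), "\n")
  invisible(x)
}

#' Binned distribution of hours spent per review
#'
#' Review durations are reported in ranges (e.g. 65% of reviews take 1 to 5
#' hours); sampling draws a bin by its probability and then a uniform value
#' on the closed interval. Every bin needs a finite upper edge: open-ended
#' top bins are not representable and must be closed at a stated maximum.
#'
#' @param lower,upper Numeric vectors of bin edges in hours,
#'   `0 <= lower <= upper < Inf`.
#' @param prob Bin probabilities, non-negative, summing to 1 within 1e-6.
#' @return An object of class `review_time_distribution` with a `bins` tibble
#'   (`lower`, `upper`, `prob`) and `mean_hours`, the bin-midpoint
#'   expectation.
#' @examples
#' review_time_distribution(c(1, 6, 11), c(5, 10, 15), c(0.65, 0.22, 0.13))
#' @export
review_time_distribution <- function(lower, upper, prob) {
  stopifnot(length(lower) == length(upper), length(lower) == length(prob))
  if (any(lower < 0)) stop("bin lower edges must be non-negative", call. = FALSE)
  if (any(!is.finite(upper))) {
    stop("every bin needs a finite upper edge (close open-ended bins at a stated maximum)",
         call. = FALSE)
  }
  if (any(upper < lower)) {
    stop("bin upper edges must not be below the lower edges", call. = FALSE)
  }
  prob <- check_probs(prob, "review-time distribution")
  structure(
    list(bins = tibble::tibble(lower = as.numeric(lower),
                               upper = as.numeric(upper),
                               prob = prob),
         mean_hours = sum(prob * (lower + upper) / 2)),
    class = "review_time_distribution"
  )
}

#' @export
print.review_time_distribution <- function(x, ...) {
  cat("Review-time distribution (hours per review):\n")
  print(x$bins)
  cat("  bin-midpoint mean:", format(x$mean_hours, digits = 6), "hours\n")
  invisible(x)
}

#' Scalar parameters of the demand model
#'
#' @param d Proportion of submissions that are desk-rejected (no external
#'   review), in `[0, 1]`. Default 0.25.
#' @param r_s Reviewers per peer-review round (may be fractional, an
#'   average), positive. Default 2.5.
#' @param beta Probability that a submission that is not desk-rejected goes
#'   through a second round of review, in `[0, 1]`. Default 0.9.
#' @param gamma Fraction of all ultimately-submitted manuscripts that remain
#'   unpublished, in `[0, 1)`. Default 0.20.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(d = 0.25, r_s = 2.5, beta = 0.9, gamma = 0.20) {
  stopifnot(is.numeric(d), length(d) == 1L,
            is.numeric(r_s), length(r_s) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  if (r_s <= 0) stop("r_s must be positive", call. = FALSE)
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)", call. = FALSE)
  structure(list(d = d, r_s = r_s, beta = beta, gamma = gamma),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters: d =", x$d, " r_s =", x$r_s,
      " beta =", x$beta, " gamma =", x$gamma, "\n")
  invisible(x)
}
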