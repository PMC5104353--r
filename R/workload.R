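#' Annual research work-time budget
#'
#' The hours a researcher has available for research in a year:
#' `hours_per_day * (days_per_year - weekend_days - holiday_days)`, truncated
#' to whole hours for a full-time researcher. Part-time budgets multiply the
#' truncated full-time figure by `research_fraction` and round half-up to
#' whole hours. With the defaults (8 h/day, 365 days, 104 weekend days, 25.3
#' holidays — an OECD average) the full-time budget is 1,885 hours; fractions
#' 0.5 and 0.3 give 943 and 566 hours.
#'
#' @param research_fraction Fraction of work time devoted to research, in
#'   `(0, 1]`. Default 1 (full-time).
#' @param hours_per_day,days_per_year,weekend_days,holiday_days Work-time
#'   convention; see defaults.
#' @return `work_time_parameters()`: an object of class
#'   `work_time_parameters`.
#' @export
work_time_parameters <- function(research_fraction = 1, hours_per_day = 8,
                                 days_per_year = 365, weekend_days = 104,
                                 holiday_days = 25.3) {
  stopifnot(hours_per_day > 0,
            research_fraction > 0, research_fraction <= 1)
  if (weekend_days + holiday_days >= days_per_year) {
    stop("weekend and holiday days must total less than the year", call. = FALSE)
  }
  structure(list(research_fraction = research_fraction,
                 hours_per_day = hours_per_day,
                 days_per_year = days_per_year,
                 weekend_days = weekend_days,
                 holiday_days = holiday_days),
            class = "work_time_parameters")
}

#' @rdname work_time_parameters
#' @param params A `work_time_parameters` object.
#' @return `research_hours()`: whole hours available for research per year.
#' @examples
#' research_hours(work_time_parameters())                           # 1885
#' research_hours(work_time_parameters(research_fraction = 0.5))    # 943
#' research_hours(work_time_parameters(research_fraction = 0.3))    # 566
#' @export
research_hours <- function(params) {
  stopifnot(inherits(params, "work_time_parameters"))
  full <- trunc(params$hours_per_day *
                  (params$days_per_year - params$weekend_days - params$holiday_days))
  hours <- if (params$research_fraction == 1) full else {
    floor(params$research_fraction * full + 0.5)  # round half-up
  }
  if (hours <= 0) stop("non-positive research-time budget", call. = FALSE)
  hours
}

#' Sample review durations from a binned distribution
#'
#' Draws a bin by its probability, then a uniform duration on the closed
#' interval `[lower, upper]` of that bin. Uses R's global RNG stream; wrap in
#' [withr::with_seed()] (or call [simulate_reviewer_workloads()], which
#' seeds) for reproducibility.
#'
#' @param dist A [review_time_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of hours, length `n`.
#' @export
sample_review_times <- function(dist, n) {
  stopifnot(inherits(dist, "review_time_distribution"), n >= 0)
  if (n == 0L) return(numeric())
  b <- dist$bins
  idx <- sample.int(nrow(b), n, replace = TRUE, prob = b$prob)
  runif(n, b$lower[idx], b$upper[idx])
}

sample_effort_counts <- function(effort, n) {
  if (n == 0L) return(integer())
  sample.int(effort$max_reviews, n, replace = TRUE, prob = effort$probs)
}

#' Monte Carlo simulation of per-reviewer annual review workload
#'
#' Each active reviewer draws an annual review count `j` from the effort
#' distribution, sums `j` independent review-duration draws, and draws a
#' work-time category (e.g. full-time / 50% / 30% research fractions) from a
#' mixture; the work-time fraction is total review hours divided by the
#' category's research-time budget. Review counts and durations are drawn
#' independently (review duration is not assumed to depend on reviewer
#' load). A single seed governs the whole simulation.
#'
#' @param n_reviewers Number of active reviewers to simulate.
#' @param effort An [effort_distribution()].
#' @param time_dist A [review_time_distribution()].
#' @param worktime A [work_time_parameters()] object or a list of them
#'   (mixture components). Default: 100% full-time.
#' @param weights Mixture weights (same length as `worktime`), summing to 1.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A tibble with one row per reviewer: `reviewer`,
#'   `reviews_completed`, `total_hours`, `t_res`, `worktime_fraction`.
#' @export
simulate_reviewer_workloads <- function(n_reviewers, effort, time_dist,
                                        worktime = work_time_parameters(),
                                        weights = NULL, seed = 1L) {
  stopifnot(n_reviewers >= 0)
  if (inherits(worktime, "work_time_parameters")) worktime <- list(worktime)
  if (is.null(weights)) weights <- rep(1 / length(worktime), length(worktime))
  stopifnot(length(weights) == length(worktime))
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("work-time mixture weights must sum to 1", call. = FALSE)
  }
  t_res_opts <- vapply(worktime, research_hours, numeric(1))
  if (n_reviewers == 0L) {
    return(tibble::tibble(reviewer = integer(), reviews_completed = integer(),
                          total_hours = numeric(), t_res = numeric(),
                          worktime_fraction = numeric()))
  }
  withr::with_seed(seed, {
    j <- sample_effort_counts(effort, n_reviewers)
    idx <- rep.int(seq_len(n_reviewers), j)
    draws <- sample_review_times(time_dist, length(idx))
    total <- numeric(n_reviewers)
    sums <- rowsum(draws, idx)
    total[as.integer(rownames(sums))] <- sums[, 1L]
    cat_idx <- if (length(t_res_opts) == 1L) rep(1L, n_reviewers) else {
      sample.int(length(t_res_opts), n_reviewers, replace = TRUE, prob = weights)
    }
  })
  t_res <- t_res_opts[cat_idx]
  tibble::tibble(reviewer = seq_len(n_reviewers), reviews_completed = j,
                 total_hours = total, t_res = t_res,
                 worktime_fraction = total / t_res)
}

#' Share of reviews performed by the top fraction of a researcher pool
#'
#' Analytic (no simulation): of a pool of `pool_size` researchers, `n_active`
#' carry annual review counts in proportion to the effort distribution and
#' the rest carry zero. Researchers are ranked by review count, and the
#' function returns the share of all reviews performed by the top
#' `floor(q * pool_size)` of them, allocating fractionally inside a tied
#' count class.
#'
#' @param pool_size Total researchers in the pool (> 0).
#' @param n_active Active reviewers, `0 < n_active <= pool_size`.
#' @param effort An [effort_distribution()].
#' @param q Top fraction, in `(0, 1]`.
#' @return Review share in `[0, 1]`.
#' @examples
#' top_share_of_reviews(2000, 1000, effort_distribution(c(`1` = 0.6, `2` = 0.4)),
#'                      0.2)  # 800/1400
#' @export
top_share_of_reviews <- function(pool_size, n_active, effort, q) {
  stopifnot(q > 0, q <= 1, n_active > 0)
  if (pool_size <= 0) stop("pool_size must be positive", call. = FALSE)
  if (n_active > pool_size) stop("n_active cannot exceed pool_size", call. = FALSE)
  j <- seq_len(effort$max_reviews)
  class_size <- c(n_active * rev(effort$probs), pool_size - n_active)
  class_reviews <- c(rev(j), 0)
  take <- floor(q * pool_size)
  taken_reviews <- 0
  remaining <- take
  for (k in seq_along(class_size)) {
    got <- min(remaining, class_size[[k]])
    taken_reviews <- taken_reviews + got * class_reviews[[k]]
    remaining <- remaining - got
    if (remaining <= 0) break
  }
  total_reviews <- n_active * effort$mean_reviews
  taken_reviews / total_reviews
}

#' Imbalance summary of simulated reviewer workloads
#'
#' Total annual review hours, hours contributed by the top `p` fraction of
#' contributors (ranked by individual hours, allocated fractionally at the
#' cut), and the proportions of reviewers whose work-time fraction falls at
#' or below a low threshold and at or above a high threshold.
#'
#' @param samples Output of [simulate_reviewer_workloads()] (needs columns
#'   `total_hours` and `worktime_fraction`).
#' @param p Top-contributor fraction, default 0.05.
#' @param threshold Low work-time fraction threshold, default 0.01.
#' @param high_threshold High work-time fraction threshold, default 0.13.
#' @return An object of class `imbalance_summary`: list with `total_hours`,
#'   `top_p_hours`, `top_p_share`, `fraction_below`, `fraction_above`, and
#'   the thresholds used.
#' @export
hours_summary <- function(samples, p = 0.05, threshold = 0.01,
                          high_threshold = 0.13) {
  if (NROW(samples) == 0L) stop("no workload samples", call. = FALSE)
  stopifnot(p > 0, p <= 1)
  hours <- sort(samples$total_hours, decreasing = TRUE)
  n_top <- p * length(hours)
  whole <- floor(n_top)
  top_p_hours <- sum(hours[seq_len(whole)])
  if (whole < length(hours) && n_top > whole) {
    top_p_hours <- top_p_hours + (n_top - whole) * hours[[whole + 1L]]
  }
  total <- sum(hours)
  structure(
    list(total_hours = total, top_p_hours = top_p_hours,
         top_p_share = top_p_hours / total, p = p,
         fraction_below = mean(samples$worktime_fraction <= threshold),
         fraction_above = mean(samples$worktime_fraction >= high_threshold),
         threshold = threshold, high_threshold = high_threshold),
    class = "imbalance_summary"
  )
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat("Peer-review workload imbalance\n")
  cat("  total hours:", format(round(x$total_hours), big.mark = ","), "\n")
  cat(sprintf("  hours by top %.0f%% of contributors: %s (%.1f%%)\n",
              100 * x$p, format(round(x$top_p_hours), big.mark = ","),
              100 * x$top_p_share))
  cat(sprintf("  reviewers at <= %.0f%% of work-time: %.1f%%\n",
              100 * x$threshold, 100 * x$fraction_below))
  cat(sprintf("  reviewers at >= %.0f%% of work-time: %.1f%%\n",
              100 * x$high_threshold, 100 * x$fraction_above))
  invisible(x)
}
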