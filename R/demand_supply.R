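#' Unpublished manuscripts implied by the unpublished fraction
#'
#' The model assumes a fraction `gamma` of all ultimately-submitted
#' manuscripts never gets published. Given the observed published count
#' `N_p`, the unpublished count solves `N_u = gamma * (N_p + N_u)`, i.e.
#' `N_u = N_p * gamma / (1 - gamma)`. The result is real-valued; rounding
#' happens only at report time.
#'
#' @param n_published Published manuscript count, non-negative.
#' @param gamma Unpublished fraction in `[0, 1)`.
#' @return Real-valued unpublished count.
#' @examples
#' unpublished_from_gamma(800, 0.20)  # 200
#' @export
unpublished_from_gamma <- function(n_published, gamma) {
  stopifnot(n_published >= 0)
  if (gamma < 0 || gamma >= 1) {
    stop("gamma must be in [0, 1): at gamma = 1 the demand is undefined",
         call. = FALSE)
  }
  n_published * gamma / (1 - gamma)
}

#' Total annual submissions
#'
#' Every published or unpublished manuscript generates submission occasions
#' according to the resubmission distribution; the model's accounting weights
#' the i-th occasion by `i` (see
#' [expected_submissions_per_manuscript()]), so
#' `N_s = (N_p + N_u) * sum_i i * R_i`.
#'
#' @param n_published,n_unpublished Manuscript counts, non-negative.
#' @param dist A [resubmission_distribution()].
#' @return Real-valued total submission count.
#' @examples
#' d <- resubmission_distribution(c(0.05, 0.10, 0.85))
#' total_submissions(800, 200, d)  # 5450
#' @export
total_submissions <- function(n_published, n_unpublished, dist) {
  stopifnot(n_published >= 0, n_unpublished >= 0)
  (n_published + n_unpublished) * expected_submissions_per_manuscript(dist)
}

#' Second-round review occasions per submission index
#'
#' `S_i = beta * (N_p + N_u) * R_i`: among manuscripts that reach an i-th
#' submission, a fraction `beta` goes through a second round of review at
#' that submission.
#'
#' @inheritParams total_submissions
#' @param beta Second-round probability in `[0, 1]`.
#' @return Numeric vector of length `dist$max_submissions`.
#' @examples
#' d <- resubmission_distribution(c(0.05, 0.10, 0.85))
#' second_round_counts(800, 200, d, 0.9)  # 900 855 765
#' @export
second_round_counts <- function(n_published, n_unpublished, dist, beta) {
  stopifnot(n_published >= 0, n_unpublished >= 0, beta >= 0, beta <= 1)
  beta * (n_published + n_unpublished) * dist$cumulative
}

#' Annual demand for reviews
#'
#' `N_reviews = (1 - d) * r_s * (N_s + sum_i S_i)`: submissions that survive
#' desk rejection each receive `r_s` reviews, and second-round occasions add
#' `r_s` more. The `(1 - d)` factor is applied to first- and second-round
#' occasions alike, exactly as the model is stated; no "corrected" variant
#' is offered.
#'
#' @param n_submissions Total submissions `N_s`, non-negative.
#' @param second_rounds Vector of second-round occasions `S_i`
#'   (see [second_round_counts()]).
#' @param params A [model_parameters()] object (uses `d` and `r_s`).
#' @return Real-valued review demand.
#' @examples
#' demand_reviews(5450, c(900, 855, 765), model_parameters())  # 14943.75
#' @export
demand_reviews <- function(n_submissions, second_rounds, params) {
  stopifnot(inherits(params, "model_parameters"),
            n_submissions >= 0, all(second_rounds >= 0))
  (1 - params$d) * params$r_s * (n_submissions + sum(second_rounds))
}

#' Mean annual reviews per active reviewer
#'
#' `sum_j P_j * j` for an effort distribution: the factor linking review
#' counts to reviewer counts on both the demand and supply side.
#'
#' @param effort An [effort_distribution()].
#' @return Scalar mean, at least 1.
#' @examples
#' expected_reviews_per_reviewer(effort_distribution(c(`1` = 0.6, `2` = 0.4)))  # 1.4
#' @export
expected_reviews_per_reviewer <- function(effort) {
  stopifnot(inherits(effort, "effort_distribution"))
  effort$mean_reviews
}

#' Annual demand for reviewers
#'
#' Inverts the effort relation: `N_reviewers = N_reviews / sum_j P_j * j`.
#' Real-valued; rounding only at report time.
#'
#' @param n_reviews Review demand, non-negative.
#' @param effort An [effort_distribution()].
#' @return Real-valued reviewer demand.
#' @examples
#' demand_reviewers(1400, effort_distribution(c(`1` = 0.6, `2` = 0.4)))  # 1000
#' @export
demand_reviewers <- function(n_reviews, effort) {
  stopifnot(n_reviews >= 0)
  m <- expected_reviews_per_reviewer(effort)
  if (m <= 0) stop("mean reviews per reviewer must be positive", call. = FALSE)
  n_reviews / m
}

#' Annual supply of reviews
#'
#' Potential reviewers (from the author census) each contribute reviews
#' according to the effort distribution:
#' `N_reviews_supply = N_reviewers_supply * sum_j P_j * j`.
#'
#' @param n_reviewers_supply Potential reviewer count, non-negative.
#' @param effort An [effort_distribution()].
#' @return Real-valued review supply.
#' @examples
#' supply_reviews(1000, effort_distribution(c(`1` = 0.6, `2` = 0.4)))  # 1400
#' @export
supply_reviews <- function(n_reviewers_supply, effort) {
  stopifnot(n_reviewers_supply >= 0)
  n_reviewers_supply * expected_reviews_per_reviewer(effort)
}

#' Relative supply-demand difference
#'
#' `100 * (supply - demand) / demand`, in percent: positive for a surplus of
#' potential reviewers (or reviews), negative for a deficit.
#'
#' @param supply,demand Non-negative scalars (or vectors); `demand` must be
#'   strictly positive.
#' @return Percentage (vectorized).
#' @examples
#' relative_difference(2.3, 2.0)  # +15
#' @export
relative_difference <- function(supply, demand) {
  if (any(demand <= 0)) {
    stop("relative difference undefined for non-positive demand", call. = FALSE)
  }
  100 * (supply - demand) / demand
}

#' Demand-side estimate for one year
#'
#' Chains the closed-form model: unpublished count from `gamma`, total
#' submissions, second-round occasions, review demand and reviewer demand.
#'
#' @param n_published Published manuscript count for the year.
#' @param dist A [resubmission_distribution()].
#' @param effort An [effort_distribution()].
#' @param params A [model_parameters()].
#' @param year Optional calendar year tag.
#' @return An object of class `demand_estimate`: a list with `year`,
#'   `n_published`, `n_unpublished`, `n_submissions`, `second_round_counts`,
#'   `n_reviews`, `n_reviewers`.
#' @export
estimate_demand <- function(n_published, dist, effort, params = model_parameters(),
                            year = NA_integer_) {
  n_u <- unpublished_from_gamma(n_published, params$gamma)
  n_s <- total_submissions(n_published, n_u, dist)
  s_i <- second_round_counts(n_published, n_u, dist, params$beta)
  n_rev <- demand_reviews(n_s, s_i, params)
  structure(
    list(year = year, n_published = n_published, n_unpublished = n_u,
         n_submissions = n_s, second_round_counts = s_i,
         n_reviews = n_rev, n_reviewers = demand_reviewers(n_rev, effort)),
    class = "demand_estimate"
  )
}

#' @export
print.demand_estimate <- function(x, ...) {
  cat("Demand estimate", if (!is.na(x$year)) paste0("(", x$year, ")"), "\n")
  cat("  published:", format(x$n_published, big.mark = ","),
      " unpublished:", format(round(x$n_unpublished), big.mark = ","), "\n")
  cat("  submissions:", format(round(x$n_submissions), big.mark = ","),
      " second rounds:", format(round(sum(x$second_round_counts)), big.mark = ","), "\n")
  cat("  reviews:", format(round(x$n_reviews), big.mark = ","),
      " reviewers:", format(round(x$n_reviewers), big.mark = ","), "\n")
  invisible(x)
}

#' Run the demand-supply comparison over years and census scenarios
#'
#' Computes the per-year demand chain and, when a census table is supplied,
#' joins the supply side (potential reviewers per year and scenario, their
#' review supply, and the relative supply-demand difference for reviewers).
#'
#' @param published A data frame with columns `year` and `n_published`, or a
#'   named numeric vector (names = years).
#' @param dist A [resubmission_distribution()].
#' @param effort An [effort_distribution()], held fixed across years.
#' @param census Optional data frame with columns `year`, `scenario`,
#'   `n_reviewers_supply`. Every published year must be covered.
#' @param params A [model_parameters()].
#' @return A tibble with one row per year (and per scenario when `census` is
#'   given): demand columns `n_published`, `n_unpublished`, `n_submissions`,
#'   `n_second_rounds`, `demand_reviews`, `demand_reviewers`, plus supply
#'   columns `n_reviewers_supply`, `supply_reviews` and
#'   `relative_difference_pct`.
#' @export
run_demand_supply <- function(published, dist, effort, census = NULL,
                              params = model_parameters()) {
  published <- as_published_table(published)
  demand <- dplyr::bind_rows(lapply(seq_len(nrow(published)), function(i) {
    est <- estimate_demand(published$n_published[[i]], dist, effort, params,
                           year = published$year[[i]])
    tibble::tibble(
      year = est$year, n_published = est$n_published,
      n_unpublished = est$n_unpublished, n_submissions = est$n_submissions,
      n_second_rounds = sum(est$second_round_counts),
      demand_reviews = est$n_reviews, demand_reviewers = est$n_reviewers
    )
  }))
  if (nrow(published) == 0L) {
    demand <- tibble::tibble(
      year = integer(), n_published = numeric(), n_unpublished = numeric(),
      n_submissions = numeric(), n_second_rounds = numeric(),
      demand_reviews = numeric(), demand_reviewers = numeric()
    )
  }
  if (is.null(census)) return(demand)
  census <- tibble::as_tibble(census)
  stopifnot(all(c("year", "scenario", "n_reviewers_supply") %in% names(census)))
  missing_years <- setdiff(demand$year, census$year)
  if (length(missing_years) > 0L) {
    stop("census table lacks years: ", paste(sort(missing_years), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::inner_join(demand, census, by = "year")
  out$supply_reviews <- supply_reviews(out$n_reviewers_supply, effort)
  # zero demand (e.g. full desk rejection) leaves the ratio undefined
  out$relative_difference_pct <- ifelse(
    out$demand_reviewers > 0,
    100 * (out$n_reviewers_supply - out$demand_reviewers) / out$demand_reviewers,
    NA_real_)
  out[order(out$year, out$scenario), ]
}

as_published_table <- function(published) {
  if (is.numeric(published) && !is.null(names(published))) {
    published <- tibble::tibble(year = as.integer(names(published)),
                                n_published = as.numeric(published))
  }
  published <- tibble::as_tibble(published)
  if (nrow(published) > 0L) {
    stopifnot(all(c("year", "n_published") %in% names(published)))
  } else if (!all(c("year", "n_published") %in% names(published))) {
    published <- tibble::tibble(year = integer(), n_published = numeric())
  }
  published
}
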