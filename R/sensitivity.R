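#' Specify a sensitivity sweep
#'
#' A sweep evaluates the demand-supply comparison over the Cartesian product
#' of parameter grids (second-round probability `beta`, unpublished fraction
#' `gamma`, desk-rejection proportion `d`), named reviewer-effort
#' distribution variants, census scenarios and years.
#'
#' @param beta,gamma,d Numeric grids; values must lie in the parameter
#'   ranges of [model_parameters()].
#' @param effort_variants Named list of [effort_distribution()] objects.
#' @param scenarios Census scenarios to include, subset of `1:4`.
#' @param years Years to include.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(beta = 0.9, gamma = 0.20, d = 0.25,
                       effort_variants, scenarios = 1:4, years) {
  stopifnot(is.list(effort_variants), length(effort_variants) >= 1L)
  if (is.null(names(effort_variants)) || any(names(effort_variants) == "")) {
    stop("effort_variants must be a named list", call. = FALSE)
  }
  for (v in effort_variants) stopifnot(inherits(v, "effort_distribution"))
  if (length(beta) == 0L || length(gamma) == 0L || length(d) == 0L ||
      length(scenarios) == 0L || length(years) == 0L) {
    stop("sweep grid is empty", call. = FALSE)
  }
  stopifnot(all(beta >= 0 & beta <= 1), all(gamma >= 0 & gamma < 1),
            all(d >= 0 & d <= 1), all(scenarios %in% 1:4))
  structure(list(beta = beta, gamma = gamma, d = d,
                 effort_variants = effort_variants,
                 scenarios = as.integer(scenarios),
                 years = as.integer(years)),
            class = "sweep_spec")
}

#' Run a sensitivity sweep
#'
#' Exhaustively evaluates [run_demand_supply()] over every cell of the sweep
#' grid. Deterministic: the singleton grid at the default parameters
#' reproduces the main analysis exactly.
#'
#' @param spec A [sweep_spec()].
#' @param published Per-year published counts (see [run_demand_supply()]).
#' @param census Supply table `year`, `scenario`, `n_reviewers_supply`.
#' @param dist The base [resubmission_distribution()].
#' @param r_s Reviewers per round, held fixed across the sweep. Default 2.5.
#' @return A tibble in long format, one row per (year, scenario, beta,
#'   gamma, d, effort variant): columns `year`, `scenario`, `beta`, `gamma`,
#'   `d`, `effort_variant`, `demand_reviews`, `demand_reviewers`,
#'   `supply_reviewers`, `supply_reviews`, `relative_difference_pct`,
#'   `balance`.
#' @export
run_sweep <- function(spec, published, census, dist, r_s = 2.5) {
  stopifnot(inherits(spec, "sweep_spec"))
  published <- as_published_table(published)
  published <- published[published$year %in% spec$years, , drop = FALSE]
  census <- tibble::as_tibble(census)
  census <- census[census$year %in% spec$years &
                     census$scenario %in% spec$scenarios, , drop = FALSE]
  cells <- expand.grid(effort_variant = names(spec$effort_variants),
                       beta = spec$beta, gamma = spec$gamma, d = spec$d,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    params <- model_parameters(d = cell$d, r_s = r_s, beta = cell$beta,
                               gamma = cell$gamma)
    tab <- run_demand_supply(published, dist,
                             spec$effort_variants[[cell$effort_variant]],
                             census = census, params = params)
    tibble::tibble(
      year = tab$year, scenario = tab$scenario,
      beta = cell$beta, gamma = cell$gamma, d = cell$d,
      effort_variant = cell$effort_variant,
      demand_reviews = tab$demand_reviews,
      demand_reviewers = tab$demand_reviewers,
      supply_reviewers = tab$n_reviewers_supply,
      supply_reviews = tab$supply_reviews,
      relative_difference_pct = tab$relative_difference_pct
    )
  })
  out <- dplyr::bind_rows(rows)
  out$balance <- surplus_flag(out$relative_difference_pct)
  out
}

#' Classify a supply-demand comparison as surplus or deficit
#'
#' Sign classification of the relative supply-demand difference. The
#' boundary (supply equal to demand, relative difference 0) is classed as
#' `"surplus"` (non-deficit).
#'
#' @param relative_difference_pct Numeric vector of relative differences in
#'   percent.
#' @return Character vector, `"surplus"` or `"deficit"`.
#' @examples
#' surplus_flag(c(15, 0, -50))  # "surplus" "surplus" "deficit"
#' @export
surplus_flag <- function(relative_difference_pct) {
  ifelse(relative_difference_pct >= 0, "surplus", "deficit")
}
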