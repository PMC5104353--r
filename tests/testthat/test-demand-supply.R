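test_that("the unpublished count solves N_u = gamma * (N_p + N_u)", {
  expect_equal(unpublished_from_gamma(800, 0.20), 200)
  expect_equal(unpublished_from_gamma(1234, 0), 0)
  expect_equal(unpublished_from_gamma(100, 0.5), 100)
  expect_error(unpublished_from_gamma(100, 1), "gamma")
})

test_that("total submissions reproduce the worked example and scale linearly", {
  d <- paper_resub()
  expect_equal(total_submissions(800, 200, d), 5450)
  expect_equal(total_submissions(0, 0, d), 0)
  withr::with_seed(11, {
    for (rep in 1:10) {
      dist <- random_resubmission()
      n <- runif(2, 0, 1e4)
      base <- total_submissions(n[1], n[2], dist)
      expect_equal(total_submissions(3 * n[1], 3 * n[2], dist), 3 * base,
                   tolerance = 1e-12)
    }
  })
})

test_that("second-round occasions are beta * (Np + Nu) * R_i", {
  d <- paper_resub()
  expect_equal(second_round_counts(800, 200, d, 0.9), c(900, 855, 765))
  expect_equal(second_round_counts(800, 200, d, 0), c(0, 0, 0))
  expect_equal(second_round_counts(1000, 0, resubmission_distribution(1), 1), 1000)
})

test_that("review demand applies (1 - d) * r_s to first and second rounds alike", {
  expect_equal(demand_reviews(5450, c(900, 855, 765), model_parameters()),
               14943.75)
  expect_equal(demand_reviews(5450, c(900, 855, 765), model_parameters(d = 1)), 0)
  expect_equal(demand_reviews(321, c(0, 0), model_parameters(d = 0, r_s = 1)), 321)
})

test_that("reviewer demand inverts the effort relation", {
  e <- paper_effort()
  expect_equal(expected_reviews_per_reviewer(e), 1.4)
  expect_equal(expected_reviews_per_reviewer(effort_distribution(c(`1` = 0.5, `4` = 0.5))),
               2.5)
  expect_equal(demand_reviewers(1400, e), 1000)
  expect_equal(demand_reviewers(0, e), 0)
  expect_equal(demand_reviewers(14943.75, e), 14943.75 / 1.4)
  expect_equal(supply_reviews(1000, e), 1400)
  expect_equal(supply_reviews(0, e), 0)
  expect_equal(supply_reviews(2000, effort_distribution(c(`1` = 0.5, `4` = 0.5))),
               5000)
})

test_that("relative supply-demand difference is a signed percentage", {
  expect_equal(relative_difference(2.3, 2.0), 15)
  expect_equal(relative_difference(5, 5), 0)
  expect_equal(relative_difference(1.0, 2.0), -50)
  expect_error(relative_difference(1, 0), "non-positive demand")
})

test_that("reviewer and review demand satisfy the effort-relation round trip", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      e <- random_effort()
      n_reviews <- runif(1, 0, 1e7)
      back <- demand_reviewers(n_reviews, e) * expected_reviews_per_reviewer(e)
      expect_equal(back, n_reviews, tolerance = 1e-9)
    }
  })
})

test_that("demand is monotone in beta, gamma, r_s and anti-monotone in d", {
  chain <- function(n_p, dist, params) {
    n_u <- unpublished_from_gamma(n_p, params$gamma)
    n_s <- total_submissions(n_p, n_u, dist)
    demand_reviews(n_s, second_round_counts(n_p, n_u, dist, params$beta), params)
  }
  withr::with_seed(31, {
    for (rep in 1:30) {
      dist <- random_resubmission()
      n_p <- runif(1, 10, 1e5)
      v <- sort(runif(2))
      base <- list(d = runif(1), r_s = runif(1, 0.5, 5), beta = runif(1),
                   gamma = runif(1, 0, 0.9))
      with_par <- function(name, value) {
        args <- base; args[[name]] <- value
        do.call(model_parameters, args)
      }
      expect_lte(chain(n_p, dist, with_par("beta", v[1])),
                 chain(n_p, dist, with_par("beta", v[2])))
      expect_lte(chain(n_p, dist, with_par("gamma", 0.9 * v[1])),
                 chain(n_p, dist, with_par("gamma", 0.9 * v[2])))
      expect_lte(chain(n_p, dist, with_par("r_s", 0.5 + v[1])),
                 chain(n_p, dist, with_par("r_s", 0.5 + v[2])))
      expect_gte(chain(n_p, dist, with_par("d", v[1])),
                 chain(n_p, dist, with_par("d", v[2])))
    }
  })
})

test_that("shifting resubmission mass toward more submissions raises demand", {
  base <- resubmission_distribution(c(0.4, 0.4, 0.2))
  shifted <- resubmission_distribution(c(0.3, 0.4, 0.3))
  params <- model_parameters()
  dem <- function(dist) {
    n_s <- total_submissions(800, 200, dist)
    demand_reviews(n_s, second_round_counts(800, 200, dist, params$beta), params)
  }
  expect_gt(dem(shifted), dem(base))
})

test_that("a manuscript-level simulator reproduces the closed forms", {
  dist <- paper_resub()
  params <- model_parameters()
  sim <- oracle_demand_simulation(1e5, dist, params, seed = 5)
  # submission accounting: closed form on the realized counts is exact
  emp <- oracle_empirical_resub(sim)
  expect_equal(total_submissions(sum(sim$counts), 0, emp),
               sim$n_submission_units, tolerance = 1e-9)
  # review demand: within 3 SE of the binomial sampling noise
  mo <- oracle_reviews_moments(sim, params)
  expect_lt(abs(sim$n_reviews - mo$mean), 3 * mo$sd)
})

test_that("the pipeline driver composes the per-operation worked examples", {
  tab <- run_demand_supply(c(`2015` = 800), paper_resub(), paper_effort(),
                           census = tibble::tibble(year = 2015L, scenario = 1L,
                                                   n_reviewers_supply = 20000),
                           params = model_parameters())
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_unpublished, 200)
  expect_equal(tab$n_submissions, 5450)
  expect_equal(tab$n_second_rounds, 900 + 855 + 765)
  expect_equal(tab$demand_reviews, 14943.75)
  expect_equal(tab$demand_reviewers, 14943.75 / 1.4)
  expect_equal(tab$supply_reviews, 20000 * 1.4)
  expect_equal(tab$relative_difference_pct,
               100 * (20000 - 14943.75 / 1.4) / (14943.75 / 1.4))
})

test_that("the pipeline driver handles empty input, repeats and missing years", {
  empty <- run_demand_supply(tibble::tibble(year = integer(),
                                            n_published = numeric()),
                             paper_resub(), paper_effort())
  expect_equal(nrow(empty), 0L)

  two <- run_demand_supply(tibble::tibble(year = c(2014L, 2015L),
                                          n_published = c(800, 800)),
                           paper_resub(), paper_effort())
  expect_equal(two$demand_reviews[[1]], two$demand_reviews[[2]])

  expect_error(
    run_demand_supply(tibble::tibble(year = c(2014L, 2015L),
                                     n_published = c(800, 800)),
                      paper_resub(), paper_effort(),
                      census = tibble::tibble(year = 2015L, scenario = 1L,
                                              n_reviewers_supply = 10)),
    "2014")
})
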