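# Brute-force, manuscript-level oracle for the closed-form demand model.
#
# Each manuscript draws its total submission count k from the exact
# resubmission probabilities. The model's accounting weights the i-th
# submission occasion by i, so a manuscript submitted k times carries
# k(k+1)/2 first-round submission units; each unit survives desk screening
# with probability (1 - d) and then receives r_s reviews. Independently,
# each of the k submission occasions triggers a second review round with
# probability beta, and — mirroring the closed form exactly as stated —
# that second round is also subjected to the (1 - d) desk factor.
oracle_demand_simulation <- function(n_manuscripts, dist, params, seed) {
  withr::with_seed(seed, {
    k <- sample.int(dist$max_submissions, n_manuscripts, replace = TRUE,
                    prob = dist$exact)
    units <- k * (k + 1) / 2
    first <- rbinom(n_manuscripts, units, 1 - params$d)
    second_rounds <- rbinom(n_manuscripts, k, params$beta)
    second <- rbinom(n_manuscripts, second_rounds, 1 - params$d)
    list(
      counts = tabulate(k, nbins = dist$max_submissions),
      n_submission_units = sum(units),
      n_occasions = sum(k),
      n_reviews = params$r_s * (sum(first) + sum(second))
    )
  })
}

# Closed-form mean and SD of the oracle's review total, conditional on the
# realized submission counts (binomial desk/second-round randomness only).
oracle_reviews_moments <- function(sim, params) {
  d <- params$d; beta <- params$beta; r_s <- params$r_s
  q2 <- beta * (1 - d)
  mean_reviews <- r_s * ((1 - d) * sim$n_submission_units + q2 * sim$n_occasions)
  var_reviews <- r_s^2 * (sim$n_submission_units * (1 - d) * d +
                            sim$n_occasions * q2 * (1 - q2))
  list(mean = mean_reviews, sd = sqrt(var_reviews))
}

# Empirical resubmission distribution realized by an oracle run.
oracle_empirical_resub <- function(sim) {
  resubmission_distribution(sim$counts / sum(sim$counts))
}

# Per-draw mean and variance of a binned uniform review-time distribution.
review_time_moments <- function(time_dist) {
  b <- time_dist$bins
  m <- (b$lower + b$upper) / 2
  second <- sum(b$prob * ((b$upper - b$lower)^2 / 12 + m^2))
  mean <- sum(b$prob * m)
  list(mean = mean, var = second - mean^2)
}
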