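#' Configuration for a synthetic publication corpus
#'
#' Describes a corpus generator that stands in for a bibliographic database:
#' a fixed pool of authors with heavy-tailed productivity (some authors
#' appear on many papers, most on few — by default lognormal appearance
#' weights), a per-paper author-count distribution, and a fixed number of
#' papers per year. Authors within one paper are sampled without
#' replacement; the same author may appear on many papers. Byline order is
#' random.
#'
#' @param n_authors Size of the author pool (> 0).
#' @param years Integer vector of calendar years to generate.
#' @param papers_per_year Papers generated per year (> 0).
#' @param authors_per_paper Probability vector over paper sizes `1..A_max`.
#'   Default: a shifted Poisson (1 + Poisson(4), truncated at 10) giving a
#'   mean of about 5 authors per paper, typical of biomedical bylines.
#' @param productivity `"lognormal"` (heavy-tailed appearance weights,
#'   `sdlog` controls the skew), `"uniform"`, or a numeric weight vector of
#'   length `n_authors`.
#' @param sdlog Log-scale SD of lognormal productivity weights. Default 1.25.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_authors, years, papers_per_year,
                          authors_per_paper = NULL,
                          productivity = c("lognormal", "uniform"),
                          sdlog = 1.25, seed = 1L) {
  stopifnot(n_authors > 0, papers_per_year > 0, length(years) >= 1L)
  if (is.null(authors_per_paper)) {
    authors_per_paper <- stats::dpois(0:9, lambda = 4)
    authors_per_paper <- authors_per_paper / sum(authors_per_paper)
  }
  authors_per_paper <- check_probs(authors_per_paper, "authors-per-paper distribution")
  if (length(authors_per_paper) > n_authors) {
    stop("authors-per-paper support exceeds the author pool", call. = FALSE)
  }
  if (!is.numeric(productivity)) {
    productivity <- match.arg(productivity)
  } else {
    stopifnot(length(productivity) == n_authors, all(productivity > 0))
  }
  structure(list(n_authors = as.integer(n_authors),
                 years = as.integer(years),
                 papers_per_year = as.integer(papers_per_year),
                 authors_per_paper = authors_per_paper,
                 productivity = productivity, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Generate a synthetic publication corpus
#'
#' For each year, generates `papers_per_year` records; each record draws an
#' author count from `authors_per_paper`, then samples that many distinct
#' authors from the pool with probability proportional to their
#' productivity weight. Identical configuration (including seed) yields a
#' byte-identical corpus.
#'
#' @param config A [corpus_config()].
#' @return A list of [publication_record()] objects.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  pool <- seq_len(config$n_authors)
  last <- sprintf("Author%05d", pool)
  fore <- sprintf("Given%05d", pool)
  init <- sprintf("G%d", pool %% 10L)
  withr::with_seed(config$seed, {
    w <- if (is.numeric(config$productivity)) {
      config$productivity
    } else if (config$productivity == "lognormal") {
      stats::rlnorm(config$n_authors, meanlog = 0, sdlog = config$sdlog)
    } else {
      rep(1, config$n_authors)
    }
    records <- vector("list", length(config$years) * config$papers_per_year)
    k <- 0L
    for (year in config$years) {
      sizes <- sample.int(length(config$authors_per_paper),
                          config$papers_per_year, replace = TRUE,
                          prob = config$authors_per_paper)
      for (s in sizes) {
        ids <- sample(pool, s, replace = FALSE, prob = w)
        k <- k + 1L
        records[[k]] <- publication_record(year, last[ids], fore[ids], init[ids])
      }
    }
  })
  records
}

#' Truncated discrete power-law effort distribution
#'
#' `P_j` proportional to `j^(-exponent)` for `j = 1..max_reviews`: a
#' heavy-tailed stand-in for empirical reviewer-effort data (on the Publons
#' platform, about 42% of reviewers reported a single review in 2015 —
#' see [calibrate_effort_exponent()] to match that anchor). `exponent = 0`
#' gives a uniform distribution; large exponents concentrate all mass on a
#' single review.
#'
#' @param exponent Power-law exponent, non-negative.
#' @param max_reviews Truncation point `J` (>= 1).
#' @return An [effort_distribution()].
#' @export
effort_from_power_law <- function(exponent, max_reviews) {
  stopifnot(exponent >= 0, max_reviews >= 1)
  j <- seq_len(max_reviews)
  effort_distribution(j^(-exponent) / sum(j^(-exponent)))
}

#' @rdname effort_from_power_law
#' @param target_p1 Desired proportion of single-review reviewers. Default
#'   0.42.
#' @param tol Bisection tolerance on the exponent.
#' @return `calibrate_effort_exponent()`: the exponent at which the
#'   normalized `P_1` equals `target_p1`, found by bisection.
#' @export
calibrate_effort_exponent <- function(target_p1 = 0.42, max_reviews = 20,
                                      tol = 1e-10) {
  stopifnot(target_p1 > 1 / max_reviews, target_p1 < 1)
  p1 <- function(a) effort_from_power_law(a, max_reviews)$probs[[1L]]
  lo <- 0; hi <- 60
  # p1 is strictly increasing in the exponent on [0, inf)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (p1(mid) < target_p1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a resubmission distribution with a target inner sum
#'
#' Builds a valid resubmission distribution on support `1..max_submissions`
#' whose demand-model inner sum `sum_i i * R_i` (see
#' [expected_submissions_per_manuscript()]) equals `mean_target`, by a
#' two-point mixture of "submitted once" and "submitted the maximum number
#' of times". Feasible targets span `[1, I(I+1)/2]` (the upper bound is the
#' inner sum of a point mass at `I`).
#'
#' @param mean_target Target inner sum.
#' @param max_submissions Support bound `I` (>= 1).
#' @return A [resubmission_distribution()].
#' @examples
#' d <- generate_resubmission(2.0, 3)
#' expected_submissions_per_manuscript(d)  # 2.0
#' @export
generate_resubmission <- function(mean_target, max_submissions) {
  stopifnot(max_submissions >= 1)
  triangular <- max_submissions * (max_submissions + 1) / 2
  if (mean_target < 1 - 1e-9 || mean_target > triangular + 1e-9) {
    stop("infeasible target: inner sum must lie in [1, ", triangular,
         "] for support 1..", max_submissions, call. = FALSE)
  }
  if (max_submissions == 1L || mean_target <= 1) {
    return(resubmission_distribution(c(1, rep(0, max_submissions - 1L))))
  }
  p1 <- 1 - (mean_target - 1) / (triangular - 1)
  exact <- numeric(max_submissions)
  exact[[1L]] <- min(max(p1, 0), 1)
  exact[[max_submissions]] <- 1 - exact[[1L]]
  resubmission_distribution(exact)
}
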