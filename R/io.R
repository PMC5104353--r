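#' Read a count-probability table
#'
#' Two-column CSV with a header: the first column is the count (submission
#' count or annual review count), the second the probability. Used for both
#' resubmission and reviewer-effort distributions.
#'
#' @param path Path to a CSV file.
#' @return A named numeric vector (names = counts).
#' @export
read_count_probability_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("expected two columns (count, probability) in ", path, call. = FALSE)
  }
  setNames(as.numeric(tab[[2L]]), as.character(as.integer(tab[[1L]])))
}

#' Read a binned review-time distribution
#'
#' Three-column CSV with header `lower_hours, upper_hours, probability`.
#'
#' @param path Path to a CSV file.
#' @return A [review_time_distribution()].
#' @export
read_review_time_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) {
    stop("expected three columns (lower_hours, upper_hours, probability) in ",
         path, call. = FALSE)
  }
  review_time_distribution(as.numeric(tab[[1L]]), as.numeric(tab[[2L]]),
                           as.numeric(tab[[3L]]))
}

#' Load all model input distributions from one config file
#'
#' The config is YAML with one block per distribution. Recognized blocks:
#' \describe{
#'   \item{resubmission}{either `exact: [p1, p2, ...]`, or
#'     `cumulative: [1, ...]`, or `csv: path` (count-probability CSV).}
#'   \item{effort}{either `probs: {1: 0.6, 2: 0.4}`, `csv: path`, or
#'     `power_law: {exponent: a, max_reviews: J}`.}
#'   \item{review_time}{either `lower`/`upper`/`prob` vectors or `csv: path`.}
#'   \item{parameters}{any of `d`, `r_s`, `beta`, `gamma` (defaults fill the
#'     rest).}
#' }
#' Relative `csv:` paths are resolved against the config file's directory.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `resubmission`, `effort`, `review_time`,
#'   `parameters` (elements are `NULL` when the block is absent).
#' @export
read_distributions_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  list(
    resubmission = build_resubmission(cfg$resubmission, base),
    effort = build_effort(cfg$effort, base),
    review_time = build_review_time(cfg$review_time, base),
    parameters = build_parameters(cfg$parameters)
  )
}

resolve_path <- function(p, base) {
  if (file.exists(p)) p else file.path(base, p)
}

build_resubmission <- function(block, base = ".") {
  if (is.null(block)) return(NULL)
  if (!is.null(block$exact)) {
    resubmission_distribution(as.numeric(unlist(block$exact)))
  } else if (!is.null(block$cumulative)) {
    resubmission_from_cumulative(as.numeric(unlist(block$cumulative)))
  } else if (!is.null(block$csv)) {
    probs <- read_count_probability_csv(resolve_path(block$csv, base))
    dense <- numeric(max(as.integer(names(probs))))
    dense[as.integer(names(probs))] <- probs
    resubmission_distribution(dense)
  } else {
    stop("resubmission block needs one of: exact, cumulative, csv", call. = FALSE)
  }
}

build_effort <- function(block, base = ".") {
  if (is.null(block)) return(NULL)
  if (!is.null(block$probs)) {
    effort_distribution(unlist(block$probs))
  } else if (!is.null(block$csv)) {
    effort_distribution(read_count_probability_csv(resolve_path(block$csv, base)))
  } else if (!is.null(block$power_law)) {
    effort_from_power_law(exponent = block$power_law$exponent,
                          max_reviews = block$power_law$max_reviews)
  } else {
    stop("effort block needs one of: probs, csv, power_law", call. = FALSE)
  }
}

build_review_time <- function(block, base = ".") {
  if (is.null(block)) return(NULL)
  if (!is.null(block$csv)) {
    read_review_time_csv(resolve_path(block$csv, base))
  } else {
    review_time_distribution(as.numeric(unlist(block$lower)),
                             as.numeric(unlist(block$upper)),
                             as.numeric(unlist(block$prob)))
  }
}

build_parameters <- function(block) {
  if (is.null(block)) return(model_parameters())
  args <- block[intersect(names(block), c("d", "r_s", "beta", "gamma"))]
  do.call(model_parameters, lapply(args, as.numeric))
}
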