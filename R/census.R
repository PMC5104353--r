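#' Publication records and author keys
#'
#' A publication record is a calendar year plus an ordered author list; each
#' author is a (last name, fore name, initials) triplet. Author identity is
#' the exact triplet after light normalization — surrounding whitespace
#' trimmed, internal whitespace runs collapsed, case-insensitive — with
#' missing fore name / initials comparing as empty strings. No algorithmic
#' name disambiguation is attempted: distinct researchers sharing a triplet
#' collapse to one key, and spelling variants of one researcher split.
#'
#' @param year Calendar year (integer).
#' @param last_name Character vector of last names (required, non-empty).
#' @param fore_name,initials Character vectors (recycled; may be empty
#'   strings for missing fields).
#' @return An object of class `publication_record`.
#' @export
publication_record <- function(year, last_name, fore_name = "", initials = "") {
  stopifnot(length(year) == 1L, is.finite(year))
  last_name <- as.character(last_name)
  if (length(last_name) == 0L || any(trimws(last_name) == "")) {
    stop("publication records need at least one author with a non-empty last name",
         call. = FALSE)
  }
  n <- length(last_name)
  structure(
    list(year = as.integer(year),
         authors = data.frame(
           last_name = last_name,
           fore_name = rep_len(as.character(fore_name), n),
           initials = rep_len(as.character(initials), n),
           stringsAsFactors = FALSE)),
    class = "publication_record"
  )
}

#' @export
print.publication_record <- function(x, ...) {
  cat("Publication record (", x$year, "): ",
      paste(x$authors$last_name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

normalize_name_field <- function(x) {
  x[is.na(x)] <- ""
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' @rdname publication_record
#' @param record A `publication_record`.
#' @return `author_keys()`: a character vector of normalized identity keys,
#'   one per author position (order preserved).
#' @export
author_keys <- function(record) {
  a <- record$authors
  paste(normalize_name_field(a$last_name),
        normalize_name_field(a$fore_name),
        normalize_name_field(a$initials), sep = "|")
}

#' Reviewer-eligible authors of one record under a census scenario
#'
#' Scenario 1: every author. Scenario 2 and 4: first and last authors.
#' Scenario 3: first, second and last authors. Positions are 1-based;
#' coinciding positions (single- or two-author papers) yield one key each.
#' (Scenarios 2 and 4 share the same positions; they differ in the census
#' time window, see [count_unique_authors()].)
#'
#' @param record A [publication_record()].
#' @param scenario Integer 1 to 4.
#' @return Character vector of unique eligible author keys.
#' @export
eligible_authors <- function(record, scenario) {
  scenario <- check_scenario(scenario)
  keys <- author_keys(record)
  n <- length(keys)
  pos <- switch(scenario,
                `1` = seq_len(n),
                `2` = c(1L, n),
                `3` = c(1L, min(2L, n), n),
                `4` = c(1L, n))
  unique(keys[unique(pos)])
}

check_scenario <- function(scenario) {
  scenario <- as.integer(scenario)
  if (length(scenario) != 1L || is.na(scenario) || scenario < 1L || scenario > 4L) {
    stop("scenario must be one of 1, 2, 3, 4", call. = FALSE)
  }
  as.character(scenario)
}

#' Count unique potential reviewers for one census year
#'
#' Counts distinct author keys among the scenario-eligible authors of all
#' records whose year falls in the window `[year - window_years + 1, year]`.
#' The window defaults to 1 year for scenarios 1, 3 and 4 and to 3 years for
#' scenario 2 (first/last authors of any article in the 3-year window ending
#' at, and including, the census year).
#'
#' @param corpus A list of [publication_record()] objects.
#' @param year Census year.
#' @param scenario Integer 1 to 4.
#' @param window_years Window length in years; defaults by scenario.
#' @return A one-row tibble: `year`, `scenario`, `n_unique_authors`.
#' @export
count_unique_authors <- function(corpus, year, scenario, window_years = NULL) {
  scen <- as.integer(scenario)
  check_scenario(scen)
  if (is.null(window_years)) window_years <- if (scen == 2L) 3L else 1L
  stopifnot(window_years >= 1L)
  years <- vapply(corpus, function(r) r$year, integer(1))
  sel <- corpus[years > year - window_years & years <= year]
  if (length(sel) == 0L) {
    warning("no records in the ", window_years, "-year window ending ", year,
            "; counting 0 potential reviewers", call. = FALSE)
    n <- 0L
  } else {
    n <- length(unique(unlist(lapply(sel, eligible_authors, scenario = scen))))
  }
  tibble::tibble(year = as.integer(year), scenario = scen, n_unique_authors = n)
}

#' Per-year, per-scenario reviewer supply from a corpus
#'
#' Convenience wrapper around [count_unique_authors()] returning the supply
#' table consumed by [run_demand_supply()].
#'
#' @param corpus A list of [publication_record()] objects.
#' @param years Census years (defaults to all years present in the corpus).
#' @param scenarios Scenario subset, default `1:4`.
#' @return A tibble `year`, `scenario`, `n_reviewers_supply`.
#' @export
census_supply <- function(corpus, years = NULL, scenarios = 1:4) {
  if (is.null(years)) {
    years <- sort(unique(vapply(corpus, function(r) r$year, integer(1))))
  }
  grid <- expand.grid(year = years, scenario = scenarios)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    count_unique_authors(corpus, grid$year[[i]], grid$scenario[[i]])
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "n_unique_authors"] <- "n_reviewers_supply"
  out[order(out$year, out$scenario), ]
}

#' Published-article counts from a corpus
#'
#' Number of records (each guaranteed to have at least one named author) in
#' a given year; this is the model's published count `N_p`.
#'
#' @param corpus A list of [publication_record()] objects.
#' @param year A single census year.
#' @return `published_count()`: an integer count.
#' @export
published_count <- function(corpus, year) {
  sum(vapply(corpus, function(r) r$year, integer(1)) == year)
}

#' @rdname published_count
#' @return `published_counts()`: a tibble `year`, `n_published` over all
#'   years present.
#' @export
published_counts <- function(corpus) {
  years <- vapply(corpus, function(r) r$year, integer(1))
  tab <- table(years)
  tibble::tibble(year = as.integer(names(tab)),
                 n_published = as.integer(tab))
}
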