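# Shared fixtures: the worked-example distributions, random-distribution
# generators for property tests, and small hand-built corpora.

paper_resub <- function() resubmission_distribution(c(0.05, 0.10, 0.85))

paper_effort <- function() effort_distribution(c(`1` = 0.6, `2` = 0.4))

paper_time_bins <- function() {
  review_time_distribution(c(1, 6, 11), c(5, 10, 15), c(0.65, 0.22, 0.13))
}

random_resubmission <- function(max_i = 6L) {
  p <- runif(sample.int(max_i, 1L))
  resubmission_distribution(p / sum(p))
}

random_effort <- function(max_j = 12L) {
  p <- runif(sample(2:max_j, 1L))
  effort_distribution(p / sum(p))
}

# Hand corpus used across census tests:
#   r1: authors A,B,C,D  r2: E,C  r3: F   (all in 2015)
hand_corpus <- function(year = 2015L) {
  list(
    publication_record(year, c("A", "B", "C", "D")),
    publication_record(year, c("E", "C")),
    publication_record(year, "F")
  )
}

small_corpus_config <- function(seed, n_authors = 60L, years = 2014:2015,
                                papers_per_year = 25L) {
  corpus_config(n_authors = n_authors, years = years,
                papers_per_year = papers_per_year,
                authors_per_paper = c(0.2, 0.3, 0.3, 0.2),
                seed = seed)
}

medline_fixture_path <- function() {
  system.file("extdata", "synthetic_medline_sample.xml", package = "peerload")
}
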