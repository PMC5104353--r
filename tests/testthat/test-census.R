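test_that("author keys normalize whitespace and case but nothing else", {
  r1 <- publication_record(2015, "  Smith  ", "John   Paul", "JP")
  r2 <- publication_record(2015, "smith", "john paul", "jp")
  expect_equal(author_keys(r1), author_keys(r2))
  r3 <- publication_record(2015, "Smith", "Jon", "JP")
  expect_false(author_keys(r3) == author_keys(r1))
  # missing fields compare as empty strings
  r4 <- publication_record(2015, "Smith")
  expect_equal(author_keys(r4), "smith||")
  expect_error(publication_record(2015, c("Ok", " ")), "non-empty last name")
  expect_error(publication_record(2015, character()), "at least one author")
})

test_that("scenario eligibility picks the stated author positions", {
  r <- publication_record(2015, c("A", "B", "C", "D"))
  expect_setequal(eligible_authors(r, 1), author_keys(r))
  expect_setequal(eligible_authors(r, 2), author_keys(r)[c(1, 4)])
  expect_setequal(eligible_authors(r, 3), author_keys(r)[c(1, 2, 4)])
  expect_setequal(eligible_authors(r, 4), author_keys(r)[c(1, 4)])
  single <- publication_record(2015, "F")
  expect_equal(eligible_authors(single, 4), author_keys(single))
  two <- publication_record(2015, c("E", "C"))
  expect_setequal(eligible_authors(two, 3), author_keys(two))
  expect_error(eligible_authors(r, 5), "scenario")
})

test_that("unique-author counts match hand enumeration on the fixture corpus", {
  corpus <- hand_corpus()
  expect_equal(count_unique_authors(corpus, 2015, 1)$n_unique_authors, 6L)
  expect_equal(count_unique_authors(corpus, 2015, 3)$n_unique_authors, 6L)
  expect_equal(count_unique_authors(corpus, 2015, 4)$n_unique_authors, 5L)
  expect_warning(res <- count_unique_authors(list(), 2015, 1), "no records")
  expect_equal(res$n_unique_authors, 0L)
})

test_that("counting is invariant under record duplication and permutation", {
  corpus <- hand_corpus()
  doubled <- c(corpus, corpus[1])
  shuffled <- corpus[c(3, 1, 2)]
  for (s in 1:4) {
    base <- count_unique_authors(corpus, 2015, s)$n_unique_authors
    expect_equal(count_unique_authors(doubled, 2015, s)$n_unique_authors, base)
    expect_equal(count_unique_authors(shuffled, 2015, s)$n_unique_authors, base)
  }
})

test_that("the scenario-2 window spans the three years ending at the census year", {
  corpus <- list(
    publication_record(2013, c("Old", "Older")),
    publication_record(2014, c("Mid", "Midder")),
    publication_record(2015, c("New", "Newer")),
    publication_record(2012, c("Ancient", "X"))
  )
  # [2013, 2015]: first/last of the three in-window records
  expect_equal(count_unique_authors(corpus, 2015, 2)$n_unique_authors, 6L)
  # scenario 4 same year only
  expect_equal(count_unique_authors(corpus, 2015, 4)$n_unique_authors, 2L)
})

test_that("scenario pools nest: 4 within 3 within 1, and 4 within 2", {
  withr::with_seed(47, {
    for (rep in 1:10) {
      corpus <- generate_corpus(small_corpus_config(seed = rep))
      yr <- 2015
      pools <- lapply(1:4, function(s) {
        years <- vapply(corpus, function(r) r$year, integer(1))
        w <- if (s == 2) 3 else 1
        sel <- corpus[years > yr - w & years <= yr]
        unique(unlist(lapply(sel, eligible_authors, scenario = s)))
      })
      expect_true(all(pools[[4]] %in% pools[[3]]))
      expect_true(all(pools[[3]] %in% pools[[1]]))
      expect_true(all(pools[[4]] %in% pools[[2]]))
    }
  })
})

test_that("published counts tally records per year and conserve the total", {
  corpus <- c(hand_corpus(2015), hand_corpus(2014)[1:2])
  expect_equal(published_count(corpus, 2015), 3L)
  expect_equal(published_count(corpus, 2013), 0L)
  tab <- published_counts(corpus)
  expect_equal(sum(tab$n_published), length(corpus))
  expect_equal(tab$n_published[tab$year == 2014], 2L)
})

test_that("census_supply builds the long supply table for the pipeline", {
  corpus <- hand_corpus()
  tab <- census_supply(corpus, years = 2015, scenarios = c(1, 4))
  expect_equal(names(tab), c("year", "scenario", "n_reviewers_supply"))
  expect_equal(tab$n_reviewers_supply[tab$scenario == 1], 6L)
  expect_equal(tab$n_reviewers_supply[tab$scenario == 4], 5L)
})

test_that("MEDLINE-style XML parses: authors kept in order, author-less records reported", {
  parsed <- parse_medline_xml(medline_fixture_path())
  expect_equal(parsed$n_total, 3L)
  expect_equal(parsed$n_records, 2L)
  expect_equal(parsed$n_excluded, 1L)
  r2015 <- parsed$records[[which(vapply(parsed$records, function(r) r$year,
                                        integer(1)) == 2015L)]]
  expect_equal(r2015$authors$last_name, c("Alpha", "Beta", "Gamma"))
  # last-name-only author keeps empty fore name and initials
  r2014 <- parsed$records[[which(vapply(parsed$records, function(r) r$year,
                                        integer(1)) == 2014L)]]
  expect_equal(r2014$authors$fore_name, "")
  expect_equal(r2014$authors$initials, "")
})

test_that("malformed XML and unknown formats raise errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><MedlineCitation>", bad)
  expect_error(parse_medline_xml(bad))
  expect_error(parse_records(medline_fixture_path(), format = "nonsense"))
})

test_that("the simple record format round-trips and skips author-less lines", {
  empty <- withr::local_tempfile(fileext = ".records")
  writeLines(character(), empty)
  expect_equal(read_records(empty)$n_records, 0L)

  corpus <- c(hand_corpus(2015), list(publication_record(2014, "Solo", "Han", "H")))
  path <- withr::local_tempfile(fileext = ".records")
  write_records(corpus, path)
  back <- read_records(path)
  expect_equal(back$n_records, length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back$records[[i]]$year, corpus[[i]]$year)
    expect_equal(back$records[[i]]$authors, corpus[[i]]$authors)
  }

  lines <- readLines(path)
  writeLines(c(lines, "2015\t"), path)   # record with no author
  expect_equal(read_records(path)$n_excluded, 1L)
})

test_that("format sniffing routes XML and record files correctly", {
  via_auto <- parse_records(medline_fixture_path())
  expect_equal(via_auto$n_records, 2L)
  path <- withr::local_tempfile(fileext = ".records")
  write_records(hand_corpus(), path)
  expect_equal(parse_records(path)$n_records, 3L)
})
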