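#' Parse publication records
#'
#' Reads a corpus of publication records from either MEDLINE/PubMed XML
#' (`MedlineCitation/Article` elements with an `AuthorList` of
#' `LastName`/`ForeName`/`Initials`) or a simple line-delimited format (one
#' record per line: `year` TAB semicolon-separated `LastName|ForeName|Initials`
#' triplets). Records without any named author are excluded and counted in
#' the parse report; authors lacking a fore name or initials keep the fields
#' they do have.
#'
#' @param path Input file path.
#' @param format `"medline-xml"`, `"records"` or `"auto"` (sniffs: a leading
#'   `<` means XML).
#' @return An object of class `corpus_parse`: a list with `records` (list of
#'   [publication_record()]), `n_records`, `n_excluded` (records dropped for
#'   having no named author) and `n_total`.
#' @export
parse_records <- function(path, format = c("auto", "medline-xml", "records")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- trimws(readChar(path, nchars = 256, useBytes = TRUE))
    format <- if (startsWith(first, "<")) "medline-xml" else "records"
  }
  switch(format,
         "medline-xml" = parse_medline_xml(path),
         "records" = read_records(path))
}

#' @rdname parse_records
#' @export
parse_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  articles <- xml2::xml_find_all(doc, "//MedlineCitation")
  records <- list()
  n_excluded <- 0L
  for (node in articles) {
    year <- medline_year(node)
    authors <- xml2::xml_find_all(node, ".//Article/AuthorList/Author")
    last <- xml2::xml_text(xml2::xml_find_first(authors, "./LastName"))
    fore <- xml2::xml_text(xml2::xml_find_first(authors, "./ForeName"))
    init <- xml2::xml_text(xml2::xml_find_first(authors, "./Initials"))
    keep <- !is.na(last) & trimws(last) != ""
    if (is.na(year) || !any(keep)) {
      n_excluded <- n_excluded + 1L
      next
    }
    fore[is.na(fore)] <- ""
    init[is.na(init)] <- ""
    records[[length(records) + 1L]] <-
      publication_record(year, last[keep], fore[keep], init[keep])
  }
  new_corpus_parse(records, n_excluded, length(articles))
}

medline_year <- function(node) {
  y <- xml2::xml_text(xml2::xml_find_first(
    node, ".//Article/Journal/JournalIssue/PubDate/Year"))
  if (is.na(y)) {
    md <- xml2::xml_text(xml2::xml_find_first(
      node, ".//Article/Journal/JournalIssue/PubDate/MedlineDate"))
    y <- regmatches(md, regexpr("[0-9]{4}", md))
    if (length(y) == 0L) return(NA_integer_)
  }
  as.integer(y)
}

#' @rdname parse_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[trimws(lines) != ""]
  records <- list()
  n_excluded <- 0L
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      n_excluded <- n_excluded + 1L
      next
    }
    year <- suppressWarnings(as.integer(parts[[1L]]))
    triplets <- strsplit(strsplit(parts[[2L]], ";", fixed = TRUE)[[1L]],
                         "|", fixed = TRUE)
    last <- vapply(triplets, function(t) t[1] %||% "", character(1))
    fore <- vapply(triplets, function(t) if (length(t) >= 2) t[[2]] else "",
                   character(1))
    init <- vapply(triplets, function(t) if (length(t) >= 3) t[[3]] else "",
                   character(1))
    keep <- !is.na(last) & trimws(last) != ""
    if (is.na(year) || !any(keep)) {
      n_excluded <- n_excluded + 1L
      next
    }
    records[[length(records) + 1L]] <-
      publication_record(year, last[keep], fore[keep], init[keep])
  }
  new_corpus_parse(records, n_excluded, length(lines))
}

new_corpus_parse <- function(records, n_excluded, n_total) {
  structure(list(records = records,
                 n_records = length(records),
                 n_excluded = n_excluded,
                 n_total = n_total),
            class = "corpus_parse")
}

#' @export
print.corpus_parse <- function(x, ...) {
  cat("Parsed corpus:", x$n_records, "records kept,",
      x$n_excluded, "excluded (no named author or no year) of",
      x$n_total, "\n")
  invisible(x)
}

#' Write publication records in the simple line format
#'
#' One record per line: `year` TAB semicolon-separated
#' `LastName|ForeName|Initials` triplets (UTF-8). Name fields must not
#' contain the `|`, `;` or TAB delimiters. Re-parsing with [read_records()]
#' round-trips the corpus.
#'
#' @param records A list of [publication_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    trip <- paste(r$authors$last_name, r$authors$fore_name, r$authors$initials,
                  sep = "|")
    paste0(r$year, "\t", paste(trip, collapse = ";"))
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
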