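write_checklist <- function(rows, sep = "\t",
                            header = c("taxon_name", "taxon_status",
                                       "taxon_authors", "first_published")) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(c(paste(header, collapse = sep),
               vapply(rows, paste, character(1), collapse = sep)), path)
  path
}

test_that("parse_checklist handles years, empty files and row order", {
  path <- write_checklist(list(
    c("Aus bus", "Accepted", "Abar.", "(1753)"),
    c("Cus dus", "Accepted", "Bevel.", ""),
    c("Eus fus", "Synonym", "Corvin.", "in Gaz. (1901) 33")))
  rec <- parse_checklist(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$publication_year, c(1753L, NA, 1901L))
  expect_equal(as.character(rec$status), c("accepted", "accepted", "other"))
  expect_equal(rec$taxon_name, c("Aus bus", "Cus dus", "Eus fus"))

  empty <- write_checklist(list())
  expect_equal(nrow(parse_checklist(empty)), 0)
})

test_that("parse_checklist detects delimiters and validates columns", {
  comma <- write_checklist(list(c("Aus bus", "Accepted", "Abar.", "(1800)")),
                           sep = ",")
  expect_equal(parse_checklist(comma)$publication_year, 1800L)
  pipe <- write_checklist(list(c("Aus bus", "Accepted", "Abar.", "(1800)")),
                          sep = "|")
  expect_equal(parse_checklist(pipe)$publication_year, 1800L)

  bad <- write_checklist(list(c("Aus bus", "Accepted", "x")),
                         header = c("taxon_name", "taxon_status", "other"))
  expect_error(parse_checklist(bad), "taxon_authors")
  expect_error(parse_checklist(tempfile()), "not found")
})

test_that("column mapping can be read from a JSON config", {
  cfg <- withr::local_tempfile(fileext = ".json")
  writeLines('{"taxon_col": "name", "accepted_value": "ok"}', cfg)
  m <- read_mapping_config(cfg)
  expect_equal(m$taxon_col, "name")
  expect_equal(m$accepted_value, "ok")
  expect_equal(m$status_col, "taxon_status")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nope": 1}', bad)
  expect_error(read_mapping_config(bad), "nope")
})

test_that("extract_authors follows botanical citation conventions", {
  # hand-labelled authority strings covering the conventions
  cases <- list(
    list("Hook.f.", c("Hook.f.")),
    list("L.", c("L.")),
    list("Hook. ex Benth.", c("Benth.")),
    list("Oliv. in Hook.f.", c("Oliv.")),
    list("(L.) Kuntze", c("L.")),
    list("(Baker) Hutch. & Dalziel", c("Baker")),
    list("A.Chev. & Hutch.", c("A.Chev.", "Hutch.")),
    list("Keay, Hepper & Stapf", c("Keay", "Hepper", "Stapf")),
    list("Baker f.", c("Baker f.")),
    list("Schumach. & Thonn.", c("Schumach.", "Thonn.")),
    list("(Hiern) Hepper", c("Hiern")),
    list("Engl. ex De Wild. & T.Durand", c("De Wild.", "T.Durand")),
    list("Stapf in Oliv.", c("Stapf")),
    list("(Schumach. & Thonn.) Taub.", c("Schumach.", "Thonn.")),
    list("Welw. ex Oliv. & Hiern", c("Oliv.", "Hiern")),
    list("P.Beauv.", c("P.Beauv.")),
    list("", character(0)),
    list(NA_character_, character(0)),
    list("Milne-Redh.", c("Milne-Redh.")),
    list("(Lam.) Benth. ex Hook.f.", c("Lam.")))
  for (cs in cases) {
    expect_setequal(extract_authors(cs[[1]]), cs[[2]])
  }
  # combining-author convention credits the parenthetical side's successor
  expect_setequal(extract_authors("(L.) Kuntze", credit = "combining"),
                  "Kuntze")
  expect_setequal(extract_authors("(Baker) Hutch. & Dalziel",
                                  credit = "combining"),
                  c("Hutch.", "Dalziel"))
})

test_that("tally_series matches a brute-force oracle and conserves records", {
  rows <- list(
    c("Aus bus", "Accepted", "Abar. & Bevel.", "(1901)"),
    c("Aus cus", "Accepted", "Abar.", "(1901)"),
    c("Aus dus", "Accepted", "Corvin.", "(1902)"),
    c("Aus eus", "Accepted", "(Dren.) Elmis.", "(1902)"),
    c("Aus fus", "Accepted", "Farrow. ex Gorse.", "(1903)"),
    c("Aus gus", "Accepted", "Gorse.", "(1903)"),
    c("Aus hus", "Accepted", "Hollin.", "(1903)"),
    c("Aus ius", "Synonym", "Ives.", "(1903)"),
    c("Aus jus", "Accepted", "Jarrah.", "(1899)"),
    c("Aus kus", "Accepted", "", "(1902)"))
  rec <- parse_checklist(write_checklist(rows))
  span <- c(1901, 1903)
  s <- tally_series(rec, span)
  oracle <- brute_tally(rec[rec$publication_year >= 1901 &
                              !is.na(rec$publication_year) &
                              rec$publication_year <= 1903, ], span)
  expect_equal(s$counts, oracle$counts)
  expect_equal(s$authors, oracle$authors)
  # conservation: accepted in-span records = sum of counts
  expect_equal(sum(s$counts), 8L)
  # permutation invariance
  set.seed(1)
  s2 <- tally_series(rec[sample(nrow(rec)), ], span)
  expect_identical(s2$counts, s$counts)
  expect_identical(s2$authors, s$authors)
})

test_that("tally_series applies the 0.1 floor and zero-fills empty years", {
  rec <- parse_checklist(write_checklist(list(
    c("Aus bus", "Accepted", "Abar. & Bevel.", "(1800)"))))
  s <- tally_series(rec, c(1799, 1801))
  expect_equal(s$counts, c(0L, 1L, 0L))
  expect_equal(s$authors, c(0.1, 2, 0.1))
  expect_true(all(s$authors >= 0.1))
})

test_that("tally_series deduplicates and filters infraspecific taxa", {
  rec <- parse_checklist(write_checklist(list(
    c("Aus bus", "Accepted", "Abar.", "(1900)"),
    c("Aus bus", "Accepted", "Abar.", "(1900)"),
    c("Aus bus var. cus", "Accepted", "Bevel.", "(1900)"),
    c("Aus dus subsp. eus", "Accepted", "Corvin.", "(1900)"))))
  expect_message(s <- tally_series(rec, c(1900, 1900)), "duplicate")
  expect_equal(s$counts, 1L)
  s_all <- suppressMessages(
    tally_series(rec, c(1900, 1900), exclude_infraspecific = FALSE))
  expect_equal(s_all$counts, 3L)
  expect_warning(tally_series(rec[0, ], c(1900, 1901)), "no accepted")
})
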