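test_that("read_corpus accepts valid rows and rejects invariant breaches", {
  rows <- rec(5)
  rows$lat[4] <- 123            # out of range
  rows$crop[5] <- "barley"      # outside vocabulary
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(rows, path)
  got <- read_corpus(path)
  expect_equal(nrow(got$records), 3)
  expect_equal(nrow(got$rejects), 2)
  expect_match(got$rejects$reason[1], "lat outside")
  expect_match(got$rejects$reason[2], "crop outside")
  # conservation: accepted + rejected = input rows
  expect_equal(nrow(got$records) + nrow(got$rejects), nrow(rows))
})

test_that("write_corpus then read_corpus is the identity on valid corpora", {
  rows <- rec(4, site_label = paste0("site", 1:4),
              Yf = c(4.5, 5.5, 6, 3.2), adaptation = c(FALSE, TRUE, FALSE, TRUE),
              adaptation_options = c("", "cultivar,irrigation", "", "fertiliser"))
  rows <- coerce_corpus_types(rows)
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(rows, path)
  back <- read_corpus(path)
  expect_equal(nrow(back$rejects), 0)
  expect_equal(back$records, rows, ignore_attr = TRUE)

  # determinism: two writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus(rows, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty corpus writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(empty_corpus(), path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_corpus(path)$records), 0)
})

test_that("column mapping validates coverage and uniqueness", {
  expect_error(column_mapping(c(study_id = "Ref No", crop = "Ref No")),
               "one source column")
  expect_error(column_mapping(c(study_id = "Ref No")), "required fields")
  expect_error(column_mapping(c(not_a_field = "X")), "unknown canonical")

  # a renaming mapping round-trips through foreign headers
  cols <- stats::setNames(paste0("col_", names(corpus_schema())),
                          names(corpus_schema()))
  m <- column_mapping(cols)
  rows <- coerce_corpus_types(rec(2, site_label = c("a", "b")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(rows, path, mapping = m)
  expect_true(all(paste0("col_", c("crop", "lat")) %in%
                    names(utils::read.csv(path, check.names = FALSE))))
  back <- read_corpus(path, mapping = m)
  expect_equal(back$records, rows, ignore_attr = TRUE)
})

test_that("missing-value codes never silently become zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- rec(3, Yb = c(5, NA, 5), dTl = NA_real_)
  write_corpus(rows, path)
  txt <- readLines(path)
  got <- read_corpus(path)$records
  expect_true(is.na(got$Yb[2]))
  expect_true(all(is.na(got$dTl)))
})

test_that("average_over_esms takes means and preserves group structure", {
  two <- rec(2, esm = c("ESM-A", "ESM-B"), YI_raw = c(-10, -20),
             Yf = c(4.5, 4.0))
  avg <- average_over_esms(two)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$YI_raw, -15)
  expect_equal(avg$esm, "ensemble_mean")

  # single-ESM group passes through except the label
  one <- rec(1, esm = "ESM-A", YI_raw = -7)
  a1 <- average_over_esms(one)
  expect_equal(a1$YI_raw, -7)
  expect_equal(a1$esm, "ensemble_mean")

  # group count preservation over distinct groups
  many <- rbind(rec(2, esm = c("A", "B"), site_label = "s1"),
                rec(3, esm = c("A", "B", "C"), site_label = "s2"),
                rec(1, site_label = "s3"))
  expect_equal(nrow(average_over_esms(many)), 3)

  # conflicting non-numeric field within a group raises
  bad <- rec(2, esm = c("A", "B"), remark = c("x", "y"))
  expect_error(average_over_esms(bad), "disagree")
})

test_that("filter_top_producers keeps the minimal covering country set", {
  prod <- data.frame(crop = "maize", country = c("A", "B", "C"),
                     share = c(0.6, 0.35, 0.05))
  rows <- rec(3, country = c("A", "B", "C"),
              scale = "country_aggregated_grid")
  kept <- filter_top_producers(rows, prod, coverage = 0.95)
  expect_setequal(kept$country, c("A", "B"))

  expect_equal(nrow(filter_top_producers(rows, prod, coverage = 1.0)), 3)

  one <- data.frame(crop = "maize", country = "A", share = 1.0)
  expect_equal(filter_top_producers(rec(1, country = "A",
                                        scale = "global_grid"),
                                    one, 0.95)$country, "A")

  # site-scale records are untouched even for minor producers
  site <- rec(1, country = "C", scale = "site")
  expect_equal(nrow(filter_top_producers(site, prod, 0.95)), 1)

  expect_error(filter_top_producers(rec(1, crop = "rice",
                                        scale = "global_grid"),
                                    prod, 0.95), "absent")
})
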