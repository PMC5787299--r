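test_that("reading collapses within-interview duplicates and keeps distinct reports", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- dplyr::bind_rows(
    rec("I1", "P1", "J1", "sp1", "boil bark"),
    rec("I1", "P1", "J1", "sp1", "boil bark"),     # duplicate
    rec("I1", "P1", "J1", "sp1", "house posts", subcat = "posts",
        major = "construction"),
    rec("I1", "P1", "J1", "sp2", "eat fruit", subcat = "fruit",
        major = "food"),
    rec("I2", "P2", "J2", "sp1", "boil bark"),
    rec("I2", "P2", "J2", "sp3", "firewood", subcat = "firewood",
        major = "fuel")
  )
  readr::write_csv(rows, path)
  expect_message(tbl <- read_interviews(path), "Collapsed 1")
  expect_equal(nrow(tbl), 5)
  expect_equal(dplyr::n_distinct(tbl$interview_id), 2)
  expect_equal(attr(tbl, "n_collapsed"), 1)
  expect_setequal(attr(tbl, "roster"), c("J1", "J2"))
})

test_that("an empty file with a header yields an empty table without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec("x", "x", "x", "x", "x")[0, ], path)
  tbl <- read_interviews(path, quiet = TRUE)
  expect_equal(nrow(tbl), 0)
})

test_that("schema remapping, missing columns, and validation errors are reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- rec("I1", "P1", "J1", "sp1", "boil bark")
  names(rows)[names(rows) == "interview_id"] <- "IntID"
  readr::write_csv(rows, path)
  expect_error(read_interviews(path, quiet = TRUE), "interview_id")
  tbl <- read_interviews(path, schema = c(interview_id = "IntID"),
                         quiet = TRUE)
  expect_equal(tbl$interview_id, "I1")

  expect_error(
    tbl_of(rec("I1", "P1", "J1", "sp1", "u", major = "sorcery")),
    "major_category")
  expect_error(
    tbl_of(rec("I1", "X", "J1", "sp1", "u"), rec("I2", "X", "J1", "sp2", "u"),
           rec("I3", "X", "J2", "sp3", "u")),
    "X")
  expect_error(
    tbl_of(rec("I1", "P1", "J9", "sp1", "u"), roster = c("J1", "J2")),
    "J9")
})

test_that("round-trip through disk preserves the report tuples exactly", {
  tbl <- random_table(8, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interviews(tbl, path)
  back <- read_interviews(path, quiet = TRUE)
  key <- c("interview_id", "informant_id", "interviewer_id", "species_id",
           "use_description", "use_subcategory", "major_category")
  expect_setequal(do.call(paste, tbl[key]), do.call(paste, back[key]))
})

test_that("repeat subset finds exactly the informants with two interviews", {
  expect_equal(nrow(repeat_subset(random_table(6, seed = 1))), 0)
  tbl <- tbl_of(rec("I1", "P1", "J1", "sp1", "u"),
                rec("I2", "P1", "J2", "sp2", "u"),
                rec("I3", "P2", "J1", "sp3", "u"))
  rs <- repeat_subset(tbl)
  expect_equal(rs$informant_id, "P1")
  expect_equal(rs$interview_1, "I1")   # lexicographic fallback, no dates
  expect_equal(rs$interviewer_2, "J2")

  sc <- scenario("null", 11)
  expect_equal(sort(repeat_subset(sc$table)$informant_id),
               sort(attr(sc$table, "repeat_roster")))
})

test_that("interviewer self rows recover the simulator's self-interviews", {
  tbl <- tbl_of(rec("I1", "J1", "J2", "sp1", "u"),
                rec("I2", "P2", "J1", "sp2", "u"), roster = c("J1", "J2"))
  sr <- interviewer_self_rows(tbl)
  expect_equal(sr$interviewer_id, "J1")
  expect_equal(sr$conducted_by, "J2")
  expect_equal(nrow(interviewer_self_rows(random_table(5, seed = 2))), 0)

  sc <- scenario("null", 5)
  selfs <- interviewer_self_rows(sc$table)
  expect_setequal(unique(selfs$interviewer_id), attr(sc$table, "roster"))
  expect_true(all(selfs$conducted_by != selfs$interviewer_id))
})

test_that("incidence rows match brute-force per-interview item recounts", {
  tbl <- tbl_of(
    rec("I1", "P1", "J1", "sp1", "boil bark"),
    rec("I1", "P1", "J1", "sp1", "house posts", subcat = "posts",
        major = "construction"))
  sp <- build_incidence(tbl, "species")
  expect_equal(unname(rowSums(sp$incidence)), 1)
  pu <- build_incidence(tbl, "plant_use")
  expect_setequal(colnames(pu$incidence),
                  c("sp1::medical", "sp1::construction"))
  expect_equal(unname(rowSums(pu$incidence)), 2)

  tbl2 <- random_table(12, seed = 7)
  for (mode in c("species", "use", "plant_use")) {
    inc <- build_incidence(tbl2, mode)
    manual <- vapply(rownames(inc$incidence), function(id) {
      rows <- tbl2[tbl2$interview_id == id, ]
      items <- switch(mode, species = rows$species_id,
                      use = rows$use_subcategory,
                      plant_use = paste(rows$species_id, rows$major_category))
      length(unique(items))
    }, numeric(1))
    expect_equal(unname(rowSums(inc$incidence)), unname(manual))
  }
})

test_that("incidence is invariant to input row order", {
  tbl <- random_table(10, seed = 9)
  shuffled <- withr::with_seed(4, tbl[sample(nrow(tbl)), ])
  a <- build_incidence(tbl, "plant_use")$incidence
  b <- build_incidence(as_interview_tbl(shuffled, quiet = TRUE),
                       "plant_use")$incidence
  expect_equal(a, b[rownames(a), colnames(a)])
})

test_that("empty interviews are kept in the table but dropped from incidence", {
  rows <- dplyr::bind_rows(rec("I1", "P1", "J1", "sp1", "u"),
                           rec("I2", "P2", "J1", NA_character_, NA))
  tbl <- as_interview_tbl(rows, quiet = TRUE)
  expect_equal(nrow(interview_meta(tbl)), 2)
  expect_warning(inc <- build_incidence(tbl, "species"), "I2")
  expect_equal(rownames(inc$incidence), "I1")
  expect_equal(inc$dropped, "I2")
})
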