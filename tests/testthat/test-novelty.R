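novelty_fixture <- function() {
  # J1's own knowledge (self-interview by J2): species A, B
  # J1 elicits I1 = {A, C}, I2 = {C, D}
  tbl_of(rec("SELF", "J1", "J2", c("A", "B"), c("uA", "uB")),
         rec("I1", "P1", "J1", c("A", "C"), c("uA", "uC")),
         rec("I2", "P2", "J1", c("C", "D"), c("uC", "uD")),
         roster = c("J1", "J2"))
}

test_that("novelty counts match the forced enumeration example", {
  nv <- novelty_counts(novelty_fixture(), "J1", "species")
  expect_equal(nv$novel_unique, 2)       # C, D
  expect_equal(nv$novel_mentions, 3)     # C twice, D once
  expect_equal(nv$same_unique, 1)        # A
  expect_equal(nv$same_mentions, 1)
  expect_equal(nv$pct_novel_unique, 100 * 2 / 3, tolerance = 1e-9)
})

test_that("own item sets honor the item class", {
  tbl <- tbl_of(rec("SELF", "J1", "J2", c("sp1", "sp2"), c("u1", "u2"),
                    subcat = c("s1", "s2"), major = c("medical", "food")),
                rec("I1", "P1", "J1", "sp9", "u9"),
                roster = c("J1", "J2"))
  expect_setequal(interviewer_own_items(tbl, "J1", "species"),
                  c("sp1", "sp2"))
  expect_setequal(interviewer_own_items(tbl, "J1", "plant_use"),
                  c("sp1::medical", "sp2::food"))
  expect_error(interviewer_own_items(tbl, "J2", "species"),
               "self-interview")
})

test_that("an empty self-interview makes everything downstream novel", {
  tbl <- tbl_of(dplyr::bind_rows(
    rec("SELF", "J1", "J2", NA_character_, NA),
    rec("I1", "P1", "J1", c("A", "B"), c("uA", "uB"))),
    roster = c("J1", "J2"))
  expect_length(interviewer_own_items(tbl, "J1", "species"), 0)
  nv <- novelty_counts(tbl, "J1", "species")
  expect_equal(nv$novel_unique, 2)
  expect_equal(nv$same_unique, 0)
  expect_equal(nv$pct_novel_unique, 100)
})

test_that("novel + same equals a brute-force recount, and growing the own set never increases novelty", {
  tbl <- random_table(15, seed = 71, n_interviewers = 3)
  # append a self-interview for J1 with a fixed own set
  own_rows <- rec("SELFJ1", "J1", "J2", c("sp01", "sp02", "sp03"),
                  c("a", "b", "c"))
  tbl <- as_interview_tbl(dplyr::bind_rows(tibble::as_tibble(tbl), own_rows),
                          quiet = TRUE)
  nv <- novelty_counts(tbl, "J1", "species")
  corpus <- tibble::as_tibble(tbl) |>
    dplyr::filter(.data$interviewer_id == "J1", .data$informant_id != "J1")
  expect_equal(nv$novel_unique + nv$same_unique,
               dplyr::n_distinct(corpus$species_id))
  expect_equal(nv$novel_mentions + nv$same_mentions,
               nrow(dplyr::distinct(corpus, .data$interview_id,
                                    .data$species_id)))
  expect_gte(nv$novel_mentions, nv$novel_unique)

  # enlarge the own set: novel_unique cannot increase
  own_rows2 <- rec("SELFJ1", "J1", "J2",
                   c("sp01", "sp02", "sp03", "sp04", "sp05"),
                   c("a", "b", "c", "d", "e"))
  tbl2 <- as_interview_tbl(
    dplyr::bind_rows(dplyr::filter(tibble::as_tibble(tbl),
                                   .data$interview_id != "SELFJ1"),
                     own_rows2), quiet = TRUE)
  nv2 <- novelty_counts(tbl2, "J1", "species")
  expect_lte(nv2$novel_unique, nv$novel_unique)
})

test_that("pool-fraction chance baseline hits its closed-form endpoints", {
  tbl <- novelty_fixture()
  # own = {A, B}, pool = {A, B, C, D}
  expect_equal(chance_novel(tbl, "J1", "species", "pool_fraction"), 50)
  tbl2 <- tbl_of(rec("SELF", "J1", "J2", c("A", "B", "C", "D"),
                     c("uA", "uB", "uC", "uD")),
                 rec("I1", "P1", "J1", c("A", "D"), c("uA", "uD")),
                 roster = c("J1", "J2"))
  expect_equal(chance_novel(tbl2, "J1", "species", "pool_fraction"), 0)
})

test_that("weighted resampling matches the exhaustive expectation under uniform weights", {
  # 10-item pool with every item mentioned exactly once study-wide, so the
  # frequency weights are uniform and the expectation over random own sets
  # of size 4 can be enumerated over all choose(10, 4) subsets
  pool_items <- sprintf("q%02d", 1:10)
  combos <- utils::combn(10, 4)
  tbl_u <- tbl_of(rec("SELF", "J1", "J2", pool_items[1:4], paste0("u", 1:4)),
                  rec("I1", "P1", "J1", pool_items[5:10], paste0("u", 5:10)),
                  roster = c("J1", "J2"))
  # pool = q01..q10 each mentioned once; elicited = q05..q10; own size 4
  exp_pct <- mean(apply(combos, 2, function(s) {
    fake_own <- pool_items[s]
    novel <- sum(!(pool_items[5:10] %in% fake_own))
    100 * novel / 6
  }))
  mc <- chance_novel(tbl_u, "J1", "species", "weighted_resample",
                     n_rep = 4000, seed = 5)
  expect_equal(mc, exp_pct, tolerance = 1)
})

test_that("published reference counts reproduce the printed novelty ranges", {
  counts <- reference_novelty_counts()
  wide <- counts |>
    dplyr::filter(.data$group == "similar") |>
    tidyr::pivot_wider(id_cols = c("interviewer", "item_class"),
                       names_from = "status", values_from = "unique")
  wide$pct <- pct_novel(wide$novel, wide$same)
  bcm_sp <- wide$pct[wide$interviewer == "BCM" & wide$item_class == "species"]
  expect_equal(round(bcm_sp, 1), 59.6)
  expect_equal(round(bcm_sp), 60)
  mov_pu <- wide$pct[wide$interviewer == "MOV" &
                       wide$item_class == "plant_use"]
  expect_equal(round(mov_pu, 1), 84.4)
})
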