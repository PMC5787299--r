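test_that("scenarios are deterministic and echo their configuration", {
  a <- scenario("null", 7)
  b <- scenario("null", 7)
  expect_identical(tibble::as_tibble(a$table), tibble::as_tibble(b$table))
  expect_identical(a$truth$pool, b$truth$pool)

  pl <- scenario_config("paper_like", 3)
  expect_equal(pl$population$n_informants, 301)
  expect_equal(pl$population$n_interviewers, 10)
  expect_error(scenario("bogus", 1), "null, pull, tighten, paper_like")
})

test_that("logistic limits of the knowledge model behave as forced", {
  base <- population_config(n_informants = 20, n_interviewers = 3,
                            n_species = 15, n_subcategories = 14,
                            plant_use_density = 0.3, competence_sd = 0,
                            age_effects = rep(0, 5), gender_effect = 0,
                            ethnicity_effect = 0, repeat_fraction = 0,
                            seed = 2)
  know_all <- base
  know_all$salience_mean <- 40
  know_all$salience_sd <- 0
  truth <- make_population(know_all)
  expect_true(all(lengths(truth$knowledge) == nrow(truth$pool)))

  know_none <- base
  know_none$salience_mean <- -40
  know_none$salience_sd <- 0
  truth0 <- make_population(know_none)
  expect_true(all(lengths(truth0$knowledge) == 0))
})

test_that("mean knowledge-set size matches the closed-form expectation", {
  cfg <- population_config(n_informants = 800, n_interviewers = 4,
                           n_species = 40, n_subcategories = 14,
                           plant_use_density = 0.3, competence_sd = 0,
                           age_effects = rep(0, 5), gender_effect = 0,
                           ethnicity_effect = 0, repeat_fraction = 0,
                           seed = 5)
  truth <- make_population(cfg)
  p <- plogis(truth$pool$salience)
  expected <- sum(p)
  mc_se <- sqrt(sum(p * (1 - p)) / cfg$n_informants)
  expect_lt(abs(mean(lengths(truth$knowledge)) - expected), 4 * mc_se)
})

test_that("no report ever leaves the informant's knowledge set", {
  sc <- scenario("pull", 23)
  truth <- sc$truth
  key <- paste(truth$pool$species_id, truth$pool$use_subcategory)
  tbl <- tibble::as_tibble(sc$table)
  tbl <- tbl[!is.na(tbl$species_id), ]
  ok <- vapply(split(tbl, tbl$informant_id), function(rows) {
    known <- key[truth$knowledge[[rows$informant_id[1]]]]
    all(paste(rows$species_id, rows$use_subcategory) %in% known)
  }, logical(1))
  expect_true(all(ok))
})

test_that("perfect recall reproduces full knowledge sets and identical repeats", {
  cfgs <- scenario_config("null", 9)
  truth <- make_population(cfgs$population)
  tab <- simulate_interviews(truth, elicitation_config(recall = 1, seed = 10))
  key <- paste(truth$pool$species_id, truth$pool$use_subcategory)
  meta <- interview_meta(tab)
  tbl <- tibble::as_tibble(tab)
  for (iid in meta$interview_id[1:10]) {
    rows <- tbl[tbl$interview_id == iid & !is.na(tbl$species_id), ]
    informant <- meta$informant_id[meta$interview_id == iid]
    expect_setequal(paste(rows$species_id, rows$use_subcategory),
                    key[truth$knowledge[[informant]]])
  }
  d <- pairwise_dissimilarity(build_incidence(tab, "plant_use"))
  ii <- intra_inter(NULL, tab, n_perm = 19, seed = 1,
                    space = "dissimilarity", d = d)
  expect_equal(ii$mean_intra, 0)
})

test_that("halving recall roughly halves reported set sizes", {
  cfgs <- scenario_config("null", 31)
  truth <- make_population(cfgs$population)
  t_half <- simulate_interviews(truth, elicitation_config(recall = 0.5,
                                                          seed = 11))
  meta <- interview_meta(t_half)
  meta$known <- lengths(truth$knowledge[meta$informant_id])
  frac <- sum(meta$n_reports) / sum(meta$known)
  mc_se <- sqrt(0.25 * sum(meta$known)) / sum(meta$known)
  expect_lt(abs(frac - 0.5), 4 * mc_se)
})

test_that("interviewer assignment gives disjoint blocks and valid repeats", {
  sc <- scenario("paper_like", 2)
  meta <- interview_meta(sc$table)
  expect_equal(dplyr::n_distinct(meta$informant_id), 301)
  expect_true(all(meta$informant_id != meta$interviewer_id))
  firsts <- meta[!duplicated(meta$informant_id), ]
  expect_equal(dplyr::n_distinct(firsts$interviewer_id), 10)
  rs <- repeat_subset(sc$table)
  expect_equal(nrow(rs), round(0.07 * 301))
  expect_true(all(rs$interviewer_1 != rs$interviewer_2))
})

test_that("higher recall shrinks intra-informant dissimilarity (common random numbers)", {
  cfgs <- scenario_config("null", 41)
  truth <- make_population(cfgs$population)
  means <- vapply(c(0.3, 0.6, 0.9), function(rho) {
    tab <- simulate_interviews(truth, elicitation_config(recall = rho,
                                                         seed = 12))
    d <- pairwise_dissimilarity(build_incidence(tab, "species"))
    suppressWarnings(intra_inter(NULL, tab, n_perm = 9, seed = 1,
                                 space = "dissimilarity", d = d)$mean_intra)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
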