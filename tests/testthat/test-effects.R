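test_that("effect vector arithmetic is exact on hand-placed coordinates", {
  fx <- effects_fixture(own = rbind(c(1, 0), c(3, 0)),
                        other = rbind(c(0, 0), c(0, 2)))
  ev <- effect_vector(fx$coords, fx$table, "J1")
  expect_equal(c(ev$v1, ev$v2), c(2, -1))
  expect_equal(ev$magnitude, sqrt(5))
  expect_equal(ev$n_pairs, 2L)

  same <- effects_fixture(own = rbind(c(1, 1), c(2, 2)),
                          other = rbind(c(2, 2), c(1, 1)))
  ev0 <- effect_vector(same$coords, same$table, "J1")
  expect_equal(c(ev0$v1, ev0$v2), c(0, 0))
  expect_error(effect_vector(fx$coords, fx$table, "J9"), "J9")
})

test_that("relabeling own and other negates vector, pull, and tighten", {
  fx <- effects_fixture(own = rbind(c(1, 0), c(3, 0), c(2, 4)),
                        other = rbind(c(0, 0), c(0, 2), c(5, 1)),
                        self_pt = c(2, 1))
  e1 <- effect_vector(fx$coords, fx$table, "J1")
  e2 <- effect_vector(fx$coords, fx$table, "J2")
  expect_equal(c(e1$v1, e1$v2), -c(e2$v1, e2$v2))
  t1 <- tighten_statistic(fx$coords, fx$table, "J1")
  t2 <- tighten_statistic(fx$coords, fx$table, "J2")
  expect_equal(t1$tighten, -t2$tighten)
})

test_that("pull reflects distances from the interviewer's own answers", {
  # self at the own-elicited centroid: maximal pull
  fx <- effects_fixture(own = rbind(c(1, 0), c(3, 0)),
                        other = rbind(c(0, 5), c(4, 5)),
                        self_pt = c(2, 0))
  ps <- pull_statistic(fx$coords, fx$table, "J1")
  expect_equal(ps$d_self_to_own, 0)
  expect_gt(ps$pull, 0)
  # self equidistant from both centroids: zero pull
  fx2 <- effects_fixture(own = rbind(c(1, 0), c(3, 0)),
                         other = rbind(c(1, 2), c(3, 2)),
                         self_pt = c(2, 1))
  expect_equal(pull_statistic(fx2$coords, fx2$table, "J1")$pull, 0)
  # no self-interview: missing, not zero
  fx3 <- effects_fixture(own = rbind(c(1, 0), c(3, 0)),
                         other = rbind(c(0, 0), c(0, 2)))
  expect_warning(ps3 <- pull_statistic(fx3$coords, fx3$table, "J1"),
                 "self-interview")
  expect_true(is.na(ps3$pull))
})

test_that("tighten compares within-partition dispersion", {
  fx <- effects_fixture(own = rbind(c(1, 1), c(1, 1)),
                        other = rbind(c(0, 0), c(4, 4)))
  ts <- tighten_statistic(fx$coords, fx$table, "J1")
  expect_equal(ts$mean_pairwise_own, 0)
  expect_gt(ts$tighten, 0)
  sym <- effects_fixture(own = rbind(c(0, 0), c(2, 2)),
                         other = rbind(c(5, 5), c(7, 7)))
  expect_equal(tighten_statistic(sym$coords, sym$table, "J1")$tighten, 0)
})

test_that("effect statistics are invariant to rigid motions of the ordination", {
  fx <- effects_fixture(own = rbind(c(1, 0), c(3, 0), c(2, 4)),
                        other = rbind(c(0, 0), c(0, 2), c(5, 1)),
                        self_pt = c(2, 1))
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(fx$coords %*% R, 2, c(3, -4), "+")
  rownames(moved) <- rownames(fx$coords)
  for (f in list(function(cc) effect_vector(cc, fx$table, "J1")$magnitude,
                 function(cc) pull_statistic(cc, fx$table, "J1")$pull,
                 function(cc) tighten_statistic(cc, fx$table, "J1")$tighten)) {
    expect_equal(f(moved), f(fx$coords), tolerance = 1e-9)
  }
})

test_that("mean inter-informant distance matches the brute-force pair mean", {
  tbl <- random_table(20, seed = 61)
  # add one repeat informant
  extra <- rec("IX1", "P01", "J1", "sp01", "u")
  tbl <- as_interview_tbl(dplyr::bind_rows(tibble::as_tibble(tbl), extra),
                          quiet = TRUE)
  X <- withr::with_seed(8, matrix(rnorm(42), 21, 2))
  rownames(X) <- sort(unique(tbl$interview_id))
  ii <- intra_inter(X, tbl, n_perm = 19, seed = 1)
  brute <- mean(as.numeric(dist(X)))
  expect_equal(ii$mean_inter, brute, tolerance = 1e-12)
  expect_equal(ii$per_informant$intra_distance,
               sqrt(sum((X["I01", ] - X["IX1", ])^2)))
})

test_that("duplicated repeat-pair coordinates give zero intra distance", {
  fx <- effects_fixture(own = rbind(c(1, 1), c(2, 2)),
                        other = rbind(c(1, 1), c(2, 2)))
  ii <- intra_inter(fx$coords, fx$table, n_perm = 19, seed = 1)
  expect_equal(ii$mean_intra, 0)
  expect_equal(ii$ratio, 0)
})

test_that("within-pair swap test floors at the add-one bound for perfect pull", {
  m <- 20   # identity swap pattern then has probability 2^-20 per draw
  own <- cbind(seq_len(m) / 20, 0)
  other <- cbind(seq_len(m) / 20 + 10, 0)
  fx <- effects_fixture(own = own, other = other, self_pt = c(0.2, 0))
  es <- effect_significance(fx$coords, fx$table, "J1", "pull",
                            n_perm = 99, seed = 3)
  expect_equal(es$p_value, 1 / 100)
  es2 <- effect_significance(fx$coords, fx$table, "J1", "pull",
                             n_perm = 99, seed = 3)
  expect_identical(es$p_value, es2$p_value)
})

test_that("significance is reported missing with a single repeat informant", {
  fx <- effects_fixture(own = rbind(c(1, 0)), other = rbind(c(0, 0)),
                        self_pt = c(1, 1))
  es <- effect_significance(fx$coords, fx$table, "J1", "magnitude",
                            n_perm = 99, seed = 1)
  expect_true(is.na(es$p_value))
})

test_that("the per-interviewer effect table assembles all statistics", {
  sc <- scenario("pull", 13)
  ord <- suppressWarnings(
    nmds(pairwise_dissimilarity(build_incidence(sc$table, "species")),
         n_restarts = 1, seed = 1, max_iter = 50, tol = 1e-4))
  eff <- suppressWarnings(interviewer_effects(ord, sc$table, n_perm = 49,
                                              seed = 2))
  expect_setequal(eff$interviewer_id, sc$truth$interviewers)
  expect_true(all(c("magnitude", "pull", "tighten", "p_pull") %in% names(eff)))
  expect_true(all(eff$magnitude >= 0))
})
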