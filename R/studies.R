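# Replicated simulation studies: calibration, recovery, and ordering checks.
# These are the package's own evaluation experiments; tests and the
# reproduction script call them against the installed package.

# one scenario replicate ordinated end to end
ordinate_scenario <- function(name, seed, mode = "species",
                              n_restarts = 2, max_iter = 100, tol = 1e-4) {
  sc <- scenario(name, seed)
  inc <- suppressWarnings(build_incidence(sc$table, mode = mode))
  d <- pairwise_dissimilarity(inc, "jaccard")
  ord <- suppressWarnings(nmds(d, k = 2, n_restarts = n_restarts, seed = seed,
                               max_iter = max_iter, tol = tol))
  list(scenario = sc, incidence = inc, d = d, ord = ord)
}

#' Does interviewer identity dominate demographics under strong bias?
#'
#' Replicates the pull scenario, ordinates each replicate, and compares the
#' interviewer-identity r-squared ([factor_r2()]) against every demographic
#' factor with at least two observed levels. Reports the proportion of
#' replicates in which interviewer identity explains the most variance.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param mode Incidence mode for the ordination.
#' @param n_restarts,max_iter NMDS settings per replicate (kept small: the
#'   comparison only needs a stable embedding, not a polished one).
#' @return List with `prop_interviewer_max`, and `per_rep` (tibble of r2
#'   values per replicate).
#' @export
study_factor_ordering <- function(n_rep = 50, seed = 1, mode = "plant_use",
                                  n_restarts = 2, max_iter = 100) {
  per_rep <- purrr::map(seq_len(n_rep), function(r) {
    run <- ordinate_scenario("pull", seed + r, mode = mode,
                             n_restarts = n_restarts, max_iter = max_iter)
    meta <- interview_meta(run$scenario$table)
    meta <- meta[match(rownames(run$ord$points), meta$interview_id), ]
    r2_int <- factor_r2(run$ord, meta$interviewer_id)
    demo <- vapply(c("gender", "age_class", "ethnicity"), function(f) {
      lab <- meta[[f]]
      if (length(unique(lab)) < 2) return(NA_real_)
      factor_r2(run$ord, lab)
    }, numeric(1))
    tibble::tibble(rep = r, r2_interviewer = r2_int,
                   r2_gender = demo[["gender"]],
                   r2_age_class = demo[["age_class"]],
                   r2_ethnicity = demo[["ethnicity"]],
                   interviewer_max = r2_int > max(demo, na.rm = TRUE))
  }) |> dplyr::bind_rows()
  list(prop_interviewer_max = mean(per_rep$interviewer_max),
       per_rep = per_rep)
}

#' Calibration of the factor permutation test under the null
#'
#' Replicates the null scenario (no interviewer bias; interviewer blocks
#' assigned at random, so interviewer identity is exchangeable), ordinates
#' each replicate, runs [fit_factor()] on interviewer identity, and reports
#' the rejection rate at level `alpha`.
#'
#' @inheritParams study_factor_ordering
#' @param n_perm Label permutations per test.
#' @param alpha Nominal level.
#' @return List with `rejection_rate`, `n_rep`, and `p_values`.
#' @export
study_null_calibration <- function(n_rep = 1000, seed = 1, n_perm = 999,
                                   alpha = 0.05, mode = "species",
                                   n_restarts = 1, max_iter = 50) {
  p_values <- vapply(seq_len(n_rep), function(r) {
    run <- ordinate_scenario("null", seed + r, mode = mode,
                             n_restarts = n_restarts, max_iter = max_iter)
    meta <- interview_meta(run$scenario$table)
    meta <- meta[match(rownames(run$ord$points), meta$interview_id), ]
    fit_factor(run$ord, meta$interviewer_id, n_perm = n_perm,
               seed = seed + r, factor_name = "interviewer_id")$p_value
  }, numeric(1))
  list(rejection_rate = mean(p_values <= alpha), n_rep = n_rep,
       p_values = p_values)
}

# the effect-calibration / bias-grid study design: few interviewers and
# many repeat interviews, so each interviewer's within-pair swap test has a
# rich permutation space and the partition means are well averaged
effect_design <- function(seed, bias = 0, narrowing = 0, recall = 0.2,
                          n_informants = 60, repeat_fraction = 0.4,
                          probe_list_size = 100) {
  list(population = population_config(
         n_informants = n_informants, n_interviewers = 4, n_species = 80,
         n_subcategories = 21, plant_use_density = 0.2,
         salience_mean = -1.0, salience_sd = 1.0, competence_sd = 0.5,
         repeat_fraction = repeat_fraction,
         probe_list_size = probe_list_size, seed = seed),
       elicitation = elicitation_config(recall = recall, bias = bias,
                                        narrowing = narrowing,
                                        seed = seed + 1))
}

ordinate_design <- function(cfgs, seed, mode = "species", n_restarts = 2,
                            max_iter = 100, tol = 1e-4,
                            truth = NULL, ordinate = TRUE) {
  if (is.null(truth)) truth <- make_population(cfgs$population)
  table <- simulate_interviews(truth, cfgs$elicitation)
  inc <- suppressWarnings(build_incidence(table, mode = mode))
  d <- pairwise_dissimilarity(inc, "jaccard")
  ord <- if (ordinate) {
    suppressWarnings(nmds(d, k = 2, n_restarts = n_restarts, seed = seed,
                          max_iter = max_iter, tol = tol))
  }
  list(truth = truth, table = table, d = d, ord = ord)
}

#' Monotone recovery of pull / tighten along a bias grid
#'
#' For each value of the chosen elicitation parameter (`bias` drives pull,
#' `narrowing` drives tighten), runs `n_rep` replicates and records the
#' replicate mean of the per-interviewer statistic; replicate `r` shares its
#' population and elicitation seed across all grid values (common random
#' numbers), so the grid is coupled. Reports the median across replicates
#' at each grid value.
#'
#' @param parameter `"bias"` (pull) or `"narrowing"` (tighten).
#' @param values Grid of parameter values.
#' @param space Geometry the statistic is measured in; the default
#'   `"dissimilarity"` avoids the attenuation of small effects by the 2-D
#'   embedding (see the methods vignette).
#' @inheritParams study_factor_ordering
#' @return List with `medians` (tibble of `value`, `median_stat`) and
#'   `per_rep` (tibble of replicate means).
#' @export
study_bias_grid <- function(parameter = c("bias", "narrowing"),
                            values = c(0, 0.5, 1, 2), n_rep = 50, seed = 1,
                            mode = "species",
                            space = c("dissimilarity", "ordination"),
                            n_restarts = 2, max_iter = 100) {
  parameter <- match.arg(parameter)
  space <- match.arg(space)
  grid_design <- function(sd_, ...) {
    effect_design(sd_, ..., n_informants = 160, repeat_fraction = 0.5)
  }
  per_rep <- purrr::map(seq_len(n_rep), function(r) {
    truth <- make_population(grid_design(seed + r)$population)
    purrr::map(values, function(v) {
      cfgs <- grid_design(seed + r,
                          bias = if (parameter == "bias") v else 0,
                          narrowing = if (parameter == "narrowing") v else 0)
      run <- ordinate_design(cfgs, seed + r, mode = mode, truth = truth,
                             n_restarts = n_restarts, max_iter = max_iter,
                             ordinate = space == "ordination")
      stats <- vapply(run$truth$interviewers, function(j) {
        row <- suppressWarnings(tryCatch(
          if (parameter == "bias") {
            pull_statistic(run$ord, run$table, j, space = space, d = run$d)
          } else {
            tighten_statistic(run$ord, run$table, j, space = space,
                              d = run$d)
          }, error = function(e) NULL))
        if (is.null(row)) return(NA_real_)
        row[[if (parameter == "bias") "pull" else "tighten"]]
      }, numeric(1))
      tibble::tibble(rep = r, value = v,
                     mean_stat = mean(stats, na.rm = TRUE))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  medians <- per_rep |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(median_stat = stats::median(.data$mean_stat),
                     .groups = "drop")
  list(medians = medians, per_rep = per_rep)
}

#' Calibration of the pull / tighten permutation tests under the null
#'
#' Replicates the unbiased effect design, ordinates each replicate, and
#' runs the within-pair swap test ([effect_significance()]) for pull and
#' tighten for every interviewer with at least `min_pairs` repeat
#' informants (a permutation test on fewer pairs cannot resolve
#' `alpha`-level significance). Rejections are pooled over interviewers and
#' replicates.
#'
#' @inheritParams study_null_calibration
#' @inheritParams study_bias_grid
#' @param min_pairs Minimum repeat informants per included test.
#' @return List with `rejection_pull`, `rejection_tighten`, `n_tests`, and
#'   the pooled `p_pull` / `p_tighten` vectors.
#' @export
study_effect_calibration <- function(n_rep = 500, seed = 1, n_perm = 199,
                                     alpha = 0.05, min_pairs = 5,
                                     mode = "species",
                                     space = c("dissimilarity", "ordination"),
                                     n_restarts = 1, max_iter = 50) {
  space <- match.arg(space)
  res <- purrr::map(seq_len(n_rep), function(r) {
    run <- ordinate_design(effect_design(seed + r), seed + r, mode = mode,
                           n_restarts = n_restarts, max_iter = max_iter,
                           ordinate = space == "ordination")
    purrr::imap(run$truth$interviewers, function(j, i) {
      part <- tryCatch(repeat_partition(run$table, j),
                       error = function(e) NULL)
      if (is.null(part) || nrow(part) < min_pairs) return(NULL)
      base <- seed + 2 * (n_rep * (i - 1) + r)
      suppressWarnings(tibble::tibble(
        rep = r, interviewer = j,
        p_pull = effect_significance(run$ord, run$table, j, "pull",
                                     n_perm = n_perm, seed = base,
                                     space = space, d = run$d)$p_value,
        p_tighten = effect_significance(run$ord, run$table, j, "tighten",
                                        n_perm = n_perm, seed = base + 1,
                                        space = space, d = run$d)$p_value))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(rejection_pull = mean(res$p_pull <= alpha, na.rm = TRUE),
       rejection_tighten = mean(res$p_tighten <= alpha, na.rm = TRUE),
       n_tests = sum(!is.na(res$p_pull)), results = res)
}

#' Intra- versus inter-informant distances in the paper-like scenario
#'
#' Replicates the paper-like scenario (low recall, mild bias), ordinates
#' each replicate, and records the [intra_inter()] permutation p-value and
#' distance ratio; also runs the degenerate perfect-recall variant
#' (`recall = 1`) once, in raw dissimilarity space, where the two
#' interviews of every informant are identical and the mean intra distance
#' is exactly zero.
#'
#' @inheritParams study_factor_ordering
#' @param n_perm Random pairings per permutation test.
#' @return List with `median_p`, `per_rep` (tibble of p-values and ratios),
#'   and `mean_intra_rho1`.
#' @export
study_intra_inter <- function(n_rep = 21, seed = 1, n_perm = 999,
                              mode = "species", n_restarts = 2,
                              max_iter = 150) {
  per_rep <- purrr::map(seq_len(n_rep), function(r) {
    run <- ordinate_scenario("paper_like", seed + r, mode = mode,
                             n_restarts = n_restarts, max_iter = max_iter)
    ii <- suppressWarnings(intra_inter(run$ord, run$scenario$table,
                                       n_perm = n_perm, seed = seed + r))
    tibble::tibble(rep = r, p_value = ii$p_value, ratio = ii$ratio,
                   mean_intra = ii$mean_intra, mean_inter = ii$mean_inter,
                   stress = run$ord$stress)
  }) |> dplyr::bind_rows()

  cfgs <- scenario_config("paper_like", seed)
  cfgs$elicitation <- elicitation_config(recall = 1, bias = 0, narrowing = 0,
                                         seed = seed + 1)
  truth <- make_population(cfgs$population)
  table1 <- simulate_interviews(truth, cfgs$elicitation)
  inc <- suppressWarnings(build_incidence(table1, mode = mode))
  d <- pairwise_dissimilarity(inc, "jaccard")
  ii1 <- suppressWarnings(intra_inter(NULL, table1, n_perm = 99, seed = seed,
                                      space = "dissimilarity", d = d))
  list(median_p = stats::median(per_rep$p_value), per_rep = per_rep,
       mean_intra_rho1 = ii1$mean_intra)
}

#' Planted-configuration recovery of the NMDS engine
#'
#' Plants `n` points in the plane, feeds their exact Euclidean distances to
#' [nmds()], and scores the result: final stress (0 for a perfectly
#' realizable rank order) and Procrustes disparity to the planted
#' configuration.
#'
#' @param n Number of planted points.
#' @param k Dimensions.
#' @param n_restarts NMDS restarts.
#' @param seed Integer seed (plants the points and seeds the restarts).
#' @return List with `stress`, `disparity`, `ord`, and `planted`.
#' @export
planted_recovery <- function(n = 20, k = 2, n_restarts = 20, seed = 1) {
  planted <- with_seed(seed, matrix(runif(n * k, -1, 1), n, k))
  d <- dist(planted)
  ord <- nmds(d, k = k, n_restarts = n_restarts, seed = seed)
  list(stress = ord$stress,
       disparity = procrustes_align(planted, ord$points)$disparity,
       ord = ord, planted = planted)
}

#' Brute-force weighted monotone regression
#'
#' Exhaustive reference for [pava_monotone()]: enumerates every partition
#' of the sequence into contiguous blocks, fits each block at its weighted
#' mean, keeps the partitions whose block means are nondecreasing, and
#' returns the feasible fit with the smallest weighted sum of squares.
#' Exponential in `length(y)`; validation use only.
#'
#' @inheritParams pava_monotone
#' @return Numeric vector: the optimal nondecreasing fit.
#' @export
pava_exhaustive <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (length(w) == 1) w <- rep(w, n)
  if (n == 1) return(stats::weighted.mean(y, w))
  best <- NULL
  best_sse <- Inf
  # each of the 2^(n-1) cut patterns defines a contiguous block partition
  for (pattern in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(pattern, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- stats::weighted.mean(y[idx], w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}
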