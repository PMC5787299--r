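# --- repeat-subset partition -------------------------------------------------

# For a focal interviewer: the repeat informants for whom they conducted one
# of the two interviews, with own/other interview ids aligned per informant.
repeat_partition <- function(x, interviewer) {
  pairs <- repeat_subset(x)
  mine <- pairs[pairs$interviewer_1 == interviewer |
                pairs$interviewer_2 == interviewer, , drop = FALSE]
  if (nrow(mine) == 0) {
    abort(sprintf("Interviewer `%s` has no repeat-subset interviews.",
                  interviewer))
  }
  first <- mine$interviewer_1 == interviewer
  tibble::tibble(
    informant_id = mine$informant_id,
    own = ifelse(first, mine$interview_1, mine$interview_2),
    other = ifelse(first, mine$interview_2, mine$interview_1)
  )
}

# drop pairs with an interview missing from the configuration (e.g. empty
# freelists excluded from the incidence matrix)
align_partition <- function(part, X, interviewer) {
  present <- part$own %in% rownames(X) & part$other %in% rownames(X)
  if (!all(present)) {
    warn(sprintf(
      "Interviewer `%s`: dropping %d repeat pair(s) absent from the ordination.",
      interviewer, sum(!present)))
    part <- part[present, , drop = FALSE]
    if (nrow(part) == 0) {
      abort(sprintf(
        "Interviewer `%s` has no repeat pair present in the ordination.",
        interviewer))
    }
  }
  part
}

coords_rows <- function(X, ids) {
  if (is.numeric(ids)) return(X[ids, , drop = FALSE])
  idx <- match(ids, rownames(X))
  if (anyNA(idx)) {
    abort(sprintf("Interview(s) absent from the ordination: %s.",
                  paste(ids[is.na(idx)], collapse = ", ")))
  }
  X[idx, , drop = FALSE]
}

mean_pairwise <- function(pts) {
  if (nrow(pts) < 2) return(NA_real_)
  mean(dist(pts))
}

# --- per-interviewer statistics ---------------------------------------------

#' Interviewer-effect vector
#'
#' For the informants interviewed twice where the focal interviewer
#' conducted one of the two interviews, the vector from the centroid of the
#' other-elicited interview locations to the centroid of the
#' interviewer-elicited locations, in ordination space. Its magnitude
#' summarizes how far the interviewer displaces the answers of the same
#' informants relative to other interviewers.
#'
#' @param coords An [nmds()] result or coordinate matrix with interview ids
#'   as rownames.
#' @param x The interview table the ordination was built from.
#' @param interviewer Focal interviewer id.
#' @return One-row tibble: `interviewer_id`, `n_pairs`, centroid columns
#'   `own_*` and `other_*`, vector components `v*`, and `magnitude`.
#' @export
effect_vector <- function(coords, x, interviewer) {
  X <- as_coords(coords)
  part <- align_partition(repeat_partition(x, interviewer), X, interviewer)
  own <- colMeans(coords_rows(X, part$own))
  other <- colMeans(coords_rows(X, part$other))
  v <- own - other
  k <- length(v)
  out <- tibble::tibble(interviewer_id = interviewer,
                        n_pairs = nrow(part))
  out[paste0("own_", seq_len(k))] <- as.list(own)
  out[paste0("other_", seq_len(k))] <- as.list(other)
  out[paste0("v", seq_len(k))] <- as.list(v)
  out$magnitude <- sqrt(sum(v^2))
  out
}

#' Pull: does an interviewer elicit answers close to their own knowledge?
#'
#' Compares the distance from the interviewer's own answers (their
#' interview-as-informant; when interviewed twice, the interview conducted
#' by someone else) to the centroid of the other-elicited interviews versus
#' the centroid of the interviews they elicited themselves, on the
#' repeat-interview subset. `pull = d(self, centroid_other) -
#' d(self, centroid_own)`; positive values mean elicited answers sit closer
#' to the interviewer's own knowledge than the other-elicited baseline.
#' Undefined (NA) when the interviewer was never interviewed.
#'
#' @inheritParams effect_vector
#' @param space Geometry the statistic is evaluated in: `"ordination"`
#'   (default; Euclidean distances to partition centroids) or
#'   `"dissimilarity"` (sensitivity analysis on the raw dissimilarities,
#'   replacing centroid distances by mean dissimilarity to the partition).
#' @param d The `dist` object the ordination was built from; required for
#'   `space = "dissimilarity"`.
#' @return One-row tibble: `interviewer_id`, `n_pairs`, `self_interview`,
#'   `d_self_to_own`, `d_self_to_other`, `pull` (NA when no
#'   self-interview exists).
#' @export
pull_statistic <- function(coords, x, interviewer,
                           space = c("ordination", "dissimilarity"),
                           d = NULL) {
  space <- match.arg(space)
  geom <- effect_geometry(coords, space, d)
  part <- align_partition(repeat_partition(x, interviewer), geom$M,
                          interviewer)
  self_id <- self_interview_of(x, interviewer)
  if (is.na(self_id) || !self_id %in% rownames(geom$M)) {
    warn(sprintf("Interviewer `%s` has no self-interview; pull is missing.",
                 interviewer))
    return(tibble::tibble(interviewer_id = interviewer, n_pairs = nrow(part),
                          self_interview = NA_character_,
                          d_self_to_own = NA_real_, d_self_to_other = NA_real_,
                          pull = NA_real_))
  }
  d_own <- self_to_partition(geom, self_id, part$own)
  d_other <- self_to_partition(geom, self_id, part$other)
  tibble::tibble(interviewer_id = interviewer, n_pairs = nrow(part),
                 self_interview = self_id,
                 d_self_to_own = d_own, d_self_to_other = d_other,
                 pull = d_other - d_own)
}

#' Tighten: does an interviewer elicit answers close to one another?
#'
#' Compares the mean pairwise distance among the interviews the focal
#' interviewer conducted (repeat subset) with the mean pairwise distance
#' among the same informants' interviews conducted by others.
#' `tighten = mean_pairwise_other - mean_pairwise_own`; positive values
#' mean the interviewer's elicited answer sets cluster more tightly.
#' Missing (NA) when either partition has fewer than 2 interviews.
#'
#' @inheritParams pull_statistic
#' @return One-row tibble: `interviewer_id`, `n_pairs`,
#'   `mean_pairwise_own`, `mean_pairwise_other`, `tighten`.
#' @export
tighten_statistic <- function(coords, x, interviewer,
                              space = c("ordination", "dissimilarity"),
                              d = NULL) {
  space <- match.arg(space)
  geom <- effect_geometry(coords, space, d)
  part <- align_partition(repeat_partition(x, interviewer), geom$M,
                          interviewer)
  own <- partition_spread(geom, part$own)
  other <- partition_spread(geom, part$other)
  if (is.na(own) || is.na(other)) {
    warn(sprintf(
      "Interviewer `%s`: a partition has < 2 interviews; tighten is missing.",
      interviewer))
  }
  tibble::tibble(interviewer_id = interviewer, n_pairs = nrow(part),
                 mean_pairwise_own = own, mean_pairwise_other = other,
                 tighten = other - own)
}

# --- permutation significance ------------------------------------------------

# geometry the statistics are evaluated in: ordination coordinates, or the
# raw dissimilarity matrix (the sensitivity-analysis switch; pull there
# uses mean dissimilarity to the partition instead of distance to centroid)
effect_geometry <- function(coords, space, d) {
  if (space == "ordination") {
    X <- as_coords(coords)
    list(space = "ordination", M = X, X = X)
  } else {
    if (is.null(d)) abort("`d` is required for space = \"dissimilarity\".")
    list(space = "dissimilarity", M = as.matrix(d), D = as.matrix(d))
  }
}

self_to_partition <- function(geom, self_id, ids) {
  if (geom$space == "ordination") {
    sqrt(sum((geom$X[self_id, ] - colMeans(coords_rows(geom$X, ids)))^2))
  } else {
    mean(geom$D[self_id, ids])
  }
}

# permutation loops index the geometry by integer position
as_row_index <- function(ids, M) {
  if (is.numeric(ids)) ids else match(ids, rownames(M))
}

partition_spread <- function(geom, ids) {
  if (length(ids) < 2) return(NA_real_)
  if (geom$space == "ordination") {
    mean_pairwise(coords_rows(geom$X, ids))
  } else {
    sub <- geom$D[ids, ids]
    mean(sub[lower.tri(sub)])
  }
}

stat_from_partition <- function(geom, own_ids, other_ids, self_id,
                                statistic) {
  switch(statistic,
    magnitude = {
      own_pts <- coords_rows(geom$X, own_ids)
      other_pts <- coords_rows(geom$X, other_ids)
      sqrt(sum((colMeans(own_pts) - colMeans(other_pts))^2))
    },
    pull = self_to_partition(geom, self_id, other_ids) -
           self_to_partition(geom, self_id, own_ids),
    tighten = partition_spread(geom, other_ids) -
              partition_spread(geom, own_ids)
  )
}

#' Permutation significance of an interviewer-effect statistic
#'
#' Under the null of no interviewer effect, which of an informant's two
#' interviews was conducted by the focal interviewer is exchangeable. The
#' test therefore swaps the own/other assignment independently within each
#' informant's interview pair, recomputes the statistic, and reports the
#' one-sided add-one p-value `(1 + #\{perm >= observed\}) / (1 + n_perm)`.
#' The published analysis this extends reported pull/tighten descriptively;
#' the permutation test is an extension of this package.
#'
#' @inheritParams pull_statistic
#' @param statistic `"pull"`, `"tighten"`, or `"magnitude"` (the
#'   effect-vector norm; ordination space only).
#' @param n_perm Number of within-pair swap permutations.
#' @param seed Integer seed.
#' @return One-row tibble: `interviewer_id`, `statistic`, `observed`,
#'   `p_value`, `n_perm`, `seed`. `p_value` is NA when the statistic is
#'   undefined or fewer than 2 repeat informants are available.
#' @export
effect_significance <- function(coords, x, interviewer,
                                statistic = c("pull", "tighten", "magnitude"),
                                n_perm = 999, seed = 1,
                                space = c("ordination", "dissimilarity"),
                                d = NULL) {
  statistic <- match.arg(statistic)
  space <- match.arg(space)
  if (statistic == "magnitude" && space == "dissimilarity") {
    abort("The effect-vector magnitude is defined in ordination space only.")
  }
  stopifnot_scalar_count(n_perm, "n_perm")
  geom <- effect_geometry(coords, space, d)
  part <- align_partition(repeat_partition(x, interviewer), geom$M,
                          interviewer)
  self_id <- NULL
  if (statistic == "pull") {
    self_id <- self_interview_of(x, interviewer)
    if (is.na(self_id) || !self_id %in% rownames(geom$M)) {
      return(tibble::tibble(interviewer_id = interviewer,
                            statistic = statistic, observed = NA_real_,
                            p_value = NA_real_, n_perm = as.integer(n_perm),
                            seed = as.integer(seed)))
    }
  }
  part$own <- as_row_index(part$own, geom$M)
  part$other <- as_row_index(part$other, geom$M)
  if (!is.null(self_id)) self_id <- as_row_index(self_id, geom$M)
  observed <- stat_from_partition(geom, part$own, part$other, self_id,
                                  statistic)
  m <- nrow(part)
  if (m < 2 || is.na(observed)) {
    return(tibble::tibble(interviewer_id = interviewer, statistic = statistic,
                          observed = observed, p_value = NA_real_,
                          n_perm = as.integer(n_perm),
                          seed = as.integer(seed)))
  }
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flip <- runif(m) < 0.5
      own <- ifelse(flip, part$other, part$own)
      other <- ifelse(flip, part$own, part$other)
      stat_from_partition(geom, own, other, self_id, statistic)
    }, numeric(1))
  })
  tibble::tibble(interviewer_id = interviewer, statistic = statistic,
                 observed = observed,
                 p_value = perm_pvalue(perm_stats, observed),
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Per-interviewer effect table
#'
#' Runs [effect_vector()], [pull_statistic()], [tighten_statistic()], and
#' (optionally) their permutation tests for every interviewer present in
#' the repeat-interview subset, returning one row per interviewer.
#' Interviewer `i` (in roster order) uses seeds `seed + 3*(i-1) + 0/1/2`
#' for the magnitude, pull, and tighten tests.
#'
#' @inheritParams effect_vector
#' @param n_perm Permutations per test; `0` skips significance entirely.
#' @param seed Base seed for the permutation tests.
#' @return A tibble with one row per interviewer: sample sizes, effect
#'   vector components and magnitude, pull and tighten with their
#'   ingredients, and `p_magnitude`, `p_pull`, `p_tighten` when requested.
#' @export
interviewer_effects <- function(coords, x, n_perm = 999, seed = 1) {
  pairs <- repeat_subset(x)
  if (nrow(pairs) == 0) abort("No repeat-interview subset in this table.")
  who <- intersect(interviewer_roster(x),
                   unique(c(pairs$interviewer_1, pairs$interviewer_2)))
  rows <- purrr::imap(who, function(j, i) {
    ev <- effect_vector(coords, x, j)
    pl <- suppressWarnings(pull_statistic(coords, x, j))
    tg <- suppressWarnings(tighten_statistic(coords, x, j))
    row <- dplyr::bind_cols(
      ev,
      pl[, c("self_interview", "d_self_to_own", "d_self_to_other", "pull")],
      tg[, c("mean_pairwise_own", "mean_pairwise_other", "tighten")]
    )
    if (n_perm > 0) {
      base <- seed + 3 * (i - 1)
      row$p_magnitude <- effect_significance(coords, x, j, "magnitude",
                                             n_perm, base)$p_value
      row$p_pull <- effect_significance(coords, x, j, "pull",
                                        n_perm, base + 1)$p_value
      row$p_tighten <- effect_significance(coords, x, j, "tighten",
                                           n_perm, base + 2)$p_value
    }
    row
  })
  dplyr::bind_rows(rows)
}

# --- intra- vs inter-informant distances -------------------------------------

#' Intra- versus inter-informant interview distances
#'
#' For each informant interviewed twice, the distance between their two
#' interview locations ("intra-informant difference"); compared against the
#' mean over all pairwise distances between interviews ("inter-informant
#' difference"). A Monte-Carlo permutation test draws `n_perm` random
#' disjoint pairings of interviews and reports the add-one p-value for the
#' hypothesis that the observed mean intra distance is smaller than the
#' mean distance of a random pairing.
#'
#' Distances are Euclidean in ordination space by default; with
#' `space = "dissimilarity"` the raw dissimilarities `d` are used instead
#' (sensitivity analysis; also the space in which two identical freelists
#' are at distance 0 exactly).
#'
#' @inheritParams effect_vector
#' @param n_perm Number of random pairings.
#' @param seed Integer seed.
#' @param space `"ordination"` (default) or `"dissimilarity"`.
#' @param d The `dist` object the ordination was built from; required for
#'   `space = "dissimilarity"`.
#' @return An object of class `intra_inter`: list with `per_informant`
#'   (tibble of per-pair distances), `mean_intra`, `mean_inter`, `ratio`,
#'   `p_value`, `n_perm`, `seed`, `space`. `tidy()` returns the per-pair
#'   tibble, `glance()` the summary row.
#' @export
intra_inter <- function(coords, x, n_perm = 999, seed = 1,
                        space = c("ordination", "dissimilarity"), d = NULL) {
  space <- match.arg(space)
  stopifnot_scalar_count(n_perm, "n_perm")
  pairs <- repeat_subset(x)
  if (nrow(pairs) == 0) abort("No repeat-interview subset in this table.")

  if (space == "ordination") {
    X <- as_coords(coords)
    ids <- rownames(X)
    D <- euclid_full(X)
    dimnames(D) <- list(ids, ids)
  } else {
    if (is.null(d)) abort("`d` is required for space = \"dissimilarity\".")
    D <- as.matrix(d)
    ids <- rownames(D)
  }
  i1 <- match(pairs$interview_1, ids)
  i2 <- match(pairs$interview_2, ids)
  gone <- is.na(i1) | is.na(i2)
  if (any(gone)) {
    warn(sprintf(
      "Dropping %d repeat pair(s) whose interviews are absent from the configuration (empty freelists).",
      sum(gone)))
    pairs <- pairs[!gone, , drop = FALSE]
    i1 <- i1[!gone]
    i2 <- i2[!gone]
    if (nrow(pairs) == 0) abort("No repeat pair present in the configuration.")
  }
  intra <- D[cbind(i1, i2)]
  mean_intra <- mean(intra)
  n <- length(ids)
  mean_inter <- mean(D[lower.tri(D)])
  m <- nrow(pairs)
  perm_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      o <- sample.int(n, 2 * m)
      mean(D[cbind(o[seq_len(m)], o[m + seq_len(m)])])
    }, numeric(1))
  })
  p_value <- (1 + sum(perm_means <= mean_intra)) / (1 + n_perm)
  structure(list(
    per_informant = tibble::tibble(informant_id = pairs$informant_id,
                                   interview_1 = pairs$interview_1,
                                   interview_2 = pairs$interview_2,
                                   intra_distance = intra),
    mean_intra = mean_intra, mean_inter = mean_inter,
    ratio = if (mean_inter > 0) mean_intra / mean_inter else NA_real_,
    p_value = p_value, n_perm = as.integer(n_perm),
    seed = as.integer(seed), space = space
  ), class = "intra_inter")
}

#' @export
print.intra_inter <- function(x, ...) {
  cat(sprintf(
    "<intra_inter> %d repeat pair(s), %s space\n  mean intra %.4f vs mean inter %.4f (ratio %.3f), p = %.4f\n",
    nrow(x$per_informant), x$space, x$mean_intra, x$mean_inter, x$ratio,
    x$p_value))
  invisible(x)
}

#' @export
tidy.intra_inter <- function(x, ...) x$per_informant

#' @export
glance.intra_inter <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$per_informant), mean_intra = x$mean_intra,
                 mean_inter = x$mean_inter, ratio = x$ratio,
                 p_value = x$p_value, n_perm = x$n_perm, space = x$space)
}
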