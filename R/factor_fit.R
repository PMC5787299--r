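# coordinates from an ordination object or a bare matrix
as_coords <- function(x) {
  if (inherits(x, "freelist_nmds")) return(x$points)
  as.matrix(x)
}

#' Variance in ordination location explained by a categorical factor
#'
#' `r2 = 1 - SS_within / SS_total` on the ordination coordinates, where
#' `SS_total` is the sum of squared Euclidean distances of the points to the
#' grand centroid and `SS_within` the sum of squared distances to the
#' centroid of each point's own factor level. This is the goodness-of-fit
#' statistic for a categorical variable fitted to ordination scores (the
#' same quantity [vegan::envfit()] reports for factors).
#'
#' @param coords An ordination ([nmds()] result) or an n x k coordinate
#'   matrix.
#' @param labels Categorical vector of length n (2 or more observed levels).
#' @return r-squared in \[0, 1\].
#' @export
factor_r2 <- function(coords, labels) {
  X <- as_coords(coords)
  labels <- droplevels(factor(labels))
  if (length(labels) != nrow(X)) abort("`labels` must match the rows of `coords`.")
  if (nlevels(labels) < 2) abort("r-squared undefined for a single-level factor.")
  Xc <- sweep(X, 2, colMeans(X))
  ss_total <- sum(Xc^2)
  if (ss_total == 0) abort("Degenerate coordinates: zero total variance.")
  r2_from_centered(Xc, labels, ss_total)
}

r2_from_centered <- function(Xc, labels, ss_total) {
  gsum <- rowsum(Xc, labels)
  gn <- tabulate(labels, nbins = nlevels(labels))
  ss_between <- sum(gsum^2 / gn)
  ss_between / ss_total
}

#' Permutation test for a factor fitted to ordination locations
#'
#' Computes [factor_r2()] and its permutation significance: labels are
#' permuted `n_perm` times and the p-value is the add-one estimator
#' `(1 + #\{permuted r2 >= observed\}) / (1 + n_perm)`. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @inheritParams factor_r2
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param factor_name Label for the output row; defaults to the expression
#'   passed as `labels`.
#' @return A one-row tibble: `factor`, `r2`, `p_value`, `n_perm`, `seed`.
#' @export
fit_factor <- function(coords, labels, n_perm = 999, seed = 1,
                       factor_name = NULL) {
  if (is.null(factor_name)) {
    factor_name <- rlang::as_label(rlang::enquo(labels))
  }
  X <- as_coords(coords)
  labels <- droplevels(factor(labels))
  if (length(labels) != nrow(X)) abort("`labels` must match the rows of `coords`.")
  if (nlevels(labels) < 2) abort("r-squared undefined for a single-level factor.")
  stopifnot_scalar_count(n_perm, "n_perm")
  Xc <- sweep(X, 2, colMeans(X))
  ss_total <- sum(Xc^2)
  if (ss_total == 0) abort("Degenerate coordinates: zero total variance.")
  observed <- r2_from_centered(Xc, labels, ss_total)
  n <- nrow(Xc)
  perm_r2 <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      r2_from_centered(Xc, labels[sample.int(n)], ss_total)
    }, numeric(1))
  })
  tibble::tibble(factor = factor_name, r2 = observed,
                 p_value = perm_pvalue(perm_r2, observed),
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Fit interviewer identity and informant demographics to an ordination
#'
#' Runs [fit_factor()] for interviewer identity, informant gender, age
#' class, and ethnicity against the same ordination coordinates. Age is
#' fitted as the 5-level categorical class, not a continuous score. Factors
#' that are constant (a single observed level) are skipped with a warning.
#' Factor `i` in `factors` uses seed `seed + i - 1`.
#'
#' @param coords An [nmds()] result or coordinate matrix with interview ids
#'   as rownames.
#' @param data An interview table, or a metadata tibble with an
#'   `interview_id` column plus the factor columns.
#' @param factors Metadata columns to fit (default interviewer identity and
#'   the three demographics).
#' @param n_perm,seed Permutation settings shared across factors.
#' @return A tibble with one row per fitted factor: `factor`, `r2`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
fit_all <- function(coords, data,
                    factors = c("interviewer_id", "gender", "age_class",
                                "ethnicity"),
                    n_perm = 999, seed = 1) {
  X <- as_coords(coords)
  meta <- if ("species_id" %in% names(data)) interview_meta(data)
          else tibble::as_tibble(data)
  if (is.null(rownames(X))) abort("`coords` must carry interview ids as rownames.")
  idx <- match(rownames(X), meta$interview_id)
  if (anyNA(idx)) {
    abort(sprintf("No metadata for interview(s): %s.",
                  paste(rownames(X)[is.na(idx)], collapse = ", ")))
  }
  meta <- meta[idx, , drop = FALSE]
  missing_cols <- setdiff(factors, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("Metadata lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- list()
  for (i in seq_along(factors)) {
    f <- factors[i]
    lab <- meta[[f]]
    if (length(unique(lab[!is.na(lab)])) < 2) {
      warn(sprintf("Skipping constant factor `%s`.", f))
      next
    }
    out[[f]] <- fit_factor(X, lab, n_perm = n_perm, seed = seed + i - 1,
                           factor_name = f)
  }
  if (!length(out)) abort("No fittable factor: all columns constant.")
  dplyr::bind_rows(out)
}
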