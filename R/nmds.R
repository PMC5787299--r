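#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' `sqrt( sum_(i<j) (dhat_ij - dist_ij)^2 / sum_(i<j) dist_ij^2 )`, where
#' `dist` are the Euclidean distances of the configuration and `dhat` is the
#' weighted least-squares monotone fit of `dist` on the rank order of the
#' input dissimilarities. Ties in the dissimilarities get the primary
#' treatment: within a tie block the configuration distances are ordered
#' ascending before the monotone fit, so tied dissimilarities may be fitted
#' by unequal distances.
#'
#' @param coords Numeric matrix, one row per object, aligned with the labels
#'   of `d`.
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @return Stress-1 in \[0, 1\].
#' @export
stress1 <- function(coords, d) {
  dvec <- as.numeric(if (inherits(d, "dist")) d else stats::as.dist(d))
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(dvec) != n * (n - 1) / 2) {
    abort("`coords` rows do not match the size of `d`.")
  }
  dconf <- lower_vec(euclid_full(coords))
  denom <- sum(dconf^2)
  if (denom == 0) return(0)
  dhat <- monotone_fit(dvec, dconf)
  sqrt(sum((dhat - dconf)^2) / denom)
}

# monotone fit of configuration distances on the rank order of the
# dissimilarities (primary tie treatment)
monotone_fit <- function(dvec, dconf) {
  o <- order(dvec, dconf)
  dhat <- numeric(length(dvec))
  dhat[o] <- .pava_cpp(dconf[o], rep(1, length(dvec)))
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Embeds interviews in `k` dimensions so that inter-point Euclidean
#' distances are (weakly) monotonically related to the input
#' dissimilarities, minimizing Kruskal stress-1 ([stress1()]). Each
#' iteration alternates a monotone-regression fit of the configuration
#' distances (pool-adjacent-violators, primary tie treatment) with a
#' majorization (Guttman-transform) update of the configuration; a
#' step-halving safeguard accepts only non-increasing stress, so the stress
#' trace is monotone by construction.
#'
#' Restart 1 initializes from classical scaling of `d` (with coincident
#' points jittered); the remaining restarts use seeded uniform random
#' coordinates. Restart `r` draws from seed `seed + r - 1`, so results are
#' reproducible and independent of the caller's RNG state. The
#' lowest-stress restart is returned, centered.
#'
#' @param d A `dist` object of dissimilarities (e.g. from
#'   [pairwise_dissimilarity()]).
#' @param k Number of dimensions (default 2).
#' @param n_restarts Number of starts (default 20); the first is classical
#'   scaling, the rest random.
#' @param seed Integer seed governing all randomness.
#' @param max_iter Maximum majorization iterations per restart.
#' @param tol Convergence: relative stress decrease below `tol`.
#' @param step_tol Convergence: configuration step norm below `step_tol`.
#' @return An object of class `freelist_nmds`: list with `points` (n x k
#'   centered coordinates, rownames = labels of `d`), `stress`, `k`,
#'   `metric`, `n_restarts`, `best_restart`, `best_restart_seed`,
#'   `iterations`, `converged`, `stress_by_restart`, and `trace` (the
#'   accepted stress sequence of the best restart).
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1,
                 max_iter = 500, tol = 1e-6, step_tol = 1e-8) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) abort("Need at least 3 objects for NMDS.")
  stopifnot_scalar_count(n_restarts, "n_restarts")
  dvec <- as.numeric(d)
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))

  best <- NULL
  stress_by_restart <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed + r - 1, {
      X0 <- if (r == 1) cmdscale_init(d, n, k) else
        matrix(runif(n * k, -0.5, 0.5), n, k)
      jitter_coincident(X0)
    })
    fit <- nmds_engine(dvec, init, max_iter = max_iter, tol = tol,
                       step_tol = step_tol)
    stress_by_restart[r] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$restart <- r
    }
  }
  if (!best$converged) {
    warn(sprintf("NMDS did not converge in %d iterations (stress %.4f).",
                 max_iter, best$stress))
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  rownames(X) <- labels
  colnames(X) <- paste0("NMDS", seq_len(k))
  structure(list(points = X, stress = best$stress, k = k,
                 metric = attr(d, "metric"), n = n,
                 n_restarts = n_restarts, best_restart = best$restart,
                 best_restart_seed = seed + best$restart - 1,
                 iterations = best$iterations, converged = best$converged,
                 stress_by_restart = stress_by_restart,
                 trace = best$trace),
            class = "freelist_nmds")
}

cmdscale_init <- function(d, n, k) {
  X0 <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(X0) < k) {
    X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
  }
  X0
}

# coincident starting points cannot separate under the Guttman transform;
# jitter the initial configuration only (never the dissimilarities)
jitter_coincident <- function(X) {
  dup <- duplicated(round(X, 12))
  if (any(dup)) {
    spread <- max(apply(X, 2, function(col) diff(range(col))), 1)
    X[dup, ] <- X[dup, ] + matrix(rnorm(sum(dup) * ncol(X), 0, 1e-4 * spread),
                                  sum(dup), ncol(X))
  }
  X
}

nmds_engine <- function(dvec, X, max_iter, tol, step_tol) {
  n <- nrow(X)
  m <- length(dvec)
  X <- scale(X, center = TRUE, scale = FALSE)
  low <- lower.tri(matrix(0, n, n))
  # start on the anchor scale (sum of squared distances = m)
  ss0 <- sum(euclid_full(X)[low]^2)
  if (ss0 > 0) X <- X * sqrt(m / ss0)

  eval_config <- function(X) {
    D <- euclid_full(X)
    dconf <- D[low]
    dhat <- monotone_fit(dvec, dconf)
    denom <- sum(dconf^2)
    stress <- if (denom == 0) 0 else sqrt(sum((dhat - dconf)^2) / denom)
    list(D = D, dhat = dhat, stress = stress)
  }

  cur <- eval_config(X)
  trace <- cur$stress
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # Guttman transform toward the monotone-fitted distances. The
    # disparities are rescaled to the constant anchor sum dhat^2 = m:
    # the raw-stress majorization otherwise contracts the whole
    # configuration geometrically, which stress-1 (scale-invariant)
    # cannot penalize.
    dhat <- cur$dhat
    ss_dhat <- sum(dhat^2)
    if (ss_dhat > 0) dhat <- dhat * sqrt(m / ss_dhat)
    Dhat <- matrix(0, n, n)
    Dhat[low] <- dhat
    Dhat <- Dhat + t(Dhat)
    ratio <- ifelse(cur$D > 0, Dhat / cur$D, 0)
    diag(ratio) <- 0
    Xnew <- (rowSums(ratio) * X - ratio %*% X) / n
    cand <- eval_config(Xnew)
    halvings <- 0
    while (cand$stress > cur$stress && halvings < 20) {
      Xnew <- (X + Xnew) / 2
      cand <- eval_config(Xnew)
      halvings <- halvings + 1
    }
    if (cand$stress > cur$stress) {
      converged <- TRUE   # no improving step in this direction
      break
    }
    step <- sqrt(sum((Xnew - X)^2))
    rel <- (cur$stress - cand$stress) / max(cur$stress, .Machine$double.eps)
    X <- Xnew
    cur <- cand
    trace <- c(trace, cur$stress)
    if (rel < tol || step < step_tol) {
      converged <- TRUE
      break
    }
  }
  list(X = X, stress = cur$stress, iterations = iter, converged = converged,
       trace = trace)
}

#' @export
print.freelist_nmds <- function(x, ...) {
  cat(sprintf(
    "<freelist_nmds> %d interviews in %d dims; stress-1 = %.4f (%s)\n",
    x$n, x$k, x$stress,
    if (x$converged) sprintf("converged in %d iterations", x$iterations)
    else "NOT converged"))
  cat(sprintf("  best of %d restart(s) (restart %d, seed %d)\n",
              x$n_restarts, x$best_restart, x$best_restart_seed))
  invisible(x)
}

#' @export
tidy.freelist_nmds <- function(x, ...) {
  out <- tibble::as_tibble(x$points)
  out$interview_id <- rownames(x$points)
  dplyr::relocate(out, "interview_id")
}

#' @export
glance.freelist_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n = x$n,
                 n_restarts = x$n_restarts, best_restart = x$best_restart,
                 iterations = x$iterations, converged = x$converged)
}
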