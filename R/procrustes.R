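#' Procrustes alignment of two configurations
#'
#' Least-squares similarity alignment of configuration `Y` onto `X`:
#' rotation (reflection allowed), uniform scaling, and translation chosen to
#' minimize the sum of squared residuals. Used to compare ordination runs
#' and to score recovery of a planted configuration. The disparity is the
#' residual sum of squares normalized by the total variance of `X`, so it is
#' 0 iff the two configurations are identical up to a similarity transform.
#'
#' @param X Target configuration (n x k matrix).
#' @param Y Configuration to align (same shape).
#' @return An object of class `procrustes_fit`: list with `rotation`
#'   (k x k orthogonal matrix), `scale` (positive real), `translation`
#'   (k-vector), `disparity`, and `yhat` (the aligned `Y`,
#'   `scale * Y %*% rotation + translation`).
#' @export
procrustes_align <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) abort("`X` and `Y` must have the same shape.")
  if (nrow(X) < 2) abort("Need at least 2 rows.")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  ssx <- sum(Xc^2)
  ssy <- sum(Yc^2)
  if (ssx == 0 || ssy == 0) abort("Degenerate configuration: all rows identical.")
  sv <- svd(crossprod(Yc, Xc))
  rotation <- sv$u %*% t(sv$v)
  scale <- sum(sv$d) / ssy
  translation <- as.numeric(cx - scale * (cy %*% rotation))
  resid <- Xc - scale * Yc %*% rotation
  disparity <- sum(resid^2) / ssx
  yhat <- sweep(scale * Y %*% rotation, 2, translation, "+")
  structure(list(rotation = rotation, scale = scale,
                 translation = translation, disparity = disparity,
                 yhat = yhat),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("<procrustes_fit> scale %.4f, disparity %.6f\n",
              x$scale, x$disparity))
  invisible(x)
}
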