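#' Weighted monotone (isotonic) regression
#'
#' Pool-adjacent-violators fit: the weighted least-squares nondecreasing
#' sequence closest to `y`. This is the monotone-regression step inside the
#' non-metric MDS engine ([nmds()]), exposed directly because its
#' correctness drives the stress computation. The fit is idempotent and
#' preserves the weighted mean of `y`.
#'
#' @param y Numeric sequence to fit.
#' @param w Positive weights, recycled if scalar.
#' @return Numeric vector of fitted values, nondecreasing, same length as
#'   `y`.
#' @examples
#' pava_monotone(c(3, 1, 2))        # -> 2 2 2
#' pava_monotone(c(1, 3, 2))        # -> 1 2.5 2.5
#' @export
pava_monotone <- function(y, w = rep(1, length(y))) {
  if (length(y) == 0) abort("`y` must have length >= 1.")
  if (length(w) == 1) w <- rep(w, length(y))
  if (length(w) != length(y)) abort("`w` must match the length of `y`.")
  if (any(!is.finite(w)) || any(w <= 0)) abort("Weights must be positive.")
  .pava_cpp(as.numeric(y), as.numeric(w))
}
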