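#' Pairwise dissimilarities between interviews
#'
#' Computes interview-by-interview dissimilarities from a presence/absence
#' incidence matrix. `"jaccard"` is 1 - |A intersect B| / |A union B|;
#' `"bray_curtis"` on 0/1 data reduces to the Sorensen dissimilarity
#' 1 - 2|A intersect B| / (|A| + |B|). Both are computed with
#' [vegan::vegdist()] in binary mode.
#'
#' @param x An `incidence_matrix` from [build_incidence()], or a 0/1 matrix
#'   with interview ids as rownames.
#' @param metric `"jaccard"` (default; presence data) or `"bray_curtis"`.
#' @return A `dist` object with interview ids as labels and attributes
#'   `metric`, `mode`, and `level` (the latter two when built from an
#'   `incidence_matrix`).
#' @export
pairwise_dissimilarity <- function(x, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  mode <- level <- NULL
  if (inherits(x, "incidence_matrix")) {
    mode <- x$mode
    level <- x$level
    m <- x$incidence
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 2) abort("Need at least 2 interviews.")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(sprintf("All-zero incidence row(s): %s.",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  d <- vegan::vegdist(m, method = if (metric == "jaccard") "jaccard" else "bray",
                      binary = TRUE)
  attr(d, "metric") <- metric
  attr(d, "mode") <- mode
  attr(d, "level") <- level
  d
}
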