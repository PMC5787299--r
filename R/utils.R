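# shared internal helpers

#' Default major use categories
#'
#' The seven major use categories used to group use subcategories: fodder,
#' fuel, medical, cultural, construction, tool, and food. The set is
#' configurable everywhere it is consumed; this is the default.
#'
#' @return Character vector of the seven category labels.
#' @export
major_categories <- function() {
  c("fodder", "fuel", "medical", "cultural", "construction", "tool", "food")
}

#' Ordered age class labels
#'
#' Five ordered adult age classes used for informant metadata.
#'
#' @return Character vector of five labels, youngest first.
#' @export
age_classes <- function() {
  c("18-30", "31-40", "41-50", "51-60", ">60")
}

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# full symmetric Euclidean distance matrix of the rows of X
euclid_full <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# lower-triangle (column-major) vector of a symmetric matrix; matches the
# element order of stats::dist
lower_vec <- function(M) M[lower.tri(M)]

# add-one permutation p-value
perm_pvalue <- function(perm_stats, observed) {
  (1 + sum(perm_stats >= observed)) / (1 + length(perm_stats))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  invisible(as.integer(x))
}
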