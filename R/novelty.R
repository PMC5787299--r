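# canonical item labels of a set of report rows, by item class
items_of <- function(rows, item_class) {
  rows <- rows[!is.na(rows$species_id), , drop = FALSE]
  switch(item_class,
    species = rows$species_id,
    use = rows$use_subcategory,
    plant_use = paste(rows$species_id, rows$major_category, sep = "::"),
    abort(sprintf("Unknown item class `%s`.", item_class))
  )
}

#' Items in an interviewer's own reported knowledge
#'
#' The set of items (species, use subcategories, or plant-use combinations)
#' the interviewer reported in their own interview-as-informant. Novelty of
#' elicited answers is counted against this set.
#'
#' @param x An interview table.
#' @param interviewer Focal interviewer id.
#' @param item_class `"species"`, `"use"`, or `"plant_use"`.
#' @return Character vector of distinct item labels (may be empty when the
#'   self-interview elicited nothing).
#' @export
interviewer_own_items <- function(x, interviewer,
                                  item_class = c("species", "use",
                                                 "plant_use")) {
  item_class <- match.arg(item_class)
  self_id <- self_interview_of(x, interviewer)
  if (is.na(self_id)) {
    abort(sprintf(
      "Interviewer `%s` has no self-interview; novelty is undefined.",
      interviewer))
  }
  tbl <- tibble::as_tibble(x)
  unique(items_of(tbl[tbl$interview_id == self_id, , drop = FALSE],
                  item_class))
}

#' Percentage of elicited items novel to the interviewer
#'
#' `100 * novel_unique / (novel_unique + same_unique)`: the share of the
#' distinct items an interviewer elicited that were absent from their own
#' reported knowledge. Vectorized; this is the computation that turns
#' published novel/same count pairs into novelty percentages.
#'
#' @param novel_unique,same_unique Non-negative counts of distinct elicited
#'   items absent from / present in the interviewer's own set.
#' @return Percentage in \[0, 100\].
#' @export
pct_novel <- function(novel_unique, same_unique) {
  total <- novel_unique + same_unique
  ifelse(total > 0, 100 * novel_unique / total, NA_real_)
}

#' Novelty counts for one interviewer and item class
#'
#' Counts, across all interviews the focal interviewer conducted (their own
#' interview-as-informant excluded), the distinct items and the
#' (interview, item) mentions that were absent from ("novel") or present in
#' ("same") the interviewer's own reported knowledge. Mentions count an
#' item once per interview in which it occurs (within-interview repetition
#' is already collapsed).
#'
#' @inheritParams interviewer_own_items
#' @return One-row tibble: `interviewer_id`, `item_class`, `novel_unique`,
#'   `novel_mentions`, `same_unique`, `same_mentions`, `pct_novel_unique`.
#' @export
novelty_counts <- function(x, interviewer,
                           item_class = c("species", "use", "plant_use")) {
  item_class <- match.arg(item_class)
  own <- interviewer_own_items(x, interviewer, item_class)
  tbl <- tibble::as_tibble(x)
  corpus <- tbl[tbl$interviewer_id == interviewer &
                tbl$informant_id != interviewer &
                !is.na(tbl$species_id), , drop = FALSE]
  if (nrow(corpus) == 0) {
    abort(sprintf("Interviewer `%s` conducted no non-self interviews.",
                  interviewer))
  }
  incid <- dplyr::distinct(
    tibble::tibble(interview_id = corpus$interview_id,
                   item = items_of(corpus, item_class)))
  novel <- !(incid$item %in% own)
  novel_unique <- length(unique(incid$item[novel]))
  same_unique <- length(unique(incid$item[!novel]))
  tibble::tibble(interviewer_id = interviewer, item_class = item_class,
                 novel_unique = novel_unique,
                 novel_mentions = sum(novel),
                 same_unique = same_unique,
                 same_mentions = sum(!novel),
                 pct_novel_unique = pct_novel(novel_unique, same_unique))
}

#' Chance-level novelty baseline
#'
#' What fraction of elicited items would look novel if the interviewer's
#' own knowledge were unrelated to what they elicit. Two interpretations
#' are provided and never silently mixed:
#' \describe{
#'   \item{`pool_fraction`}{`100 * (|pool| - |own|) / |pool|`: the share of
#'     the study-wide item pool outside the interviewer's own set.}
#'   \item{`weighted_resample`}{Monte-Carlo expectation of
#'     `pct_novel_unique` when the own set is replaced by an equal-size
#'     random set drawn (without replacement) from the pool with
#'     probability proportional to study-wide mention frequency.}
#' }
#'
#' @inheritParams interviewer_own_items
#' @param method Baseline definition (see Details).
#' @param n_rep Monte-Carlo replicates for `weighted_resample`.
#' @param seed Integer seed for `weighted_resample`.
#' @return Baseline percentage in \[0, 100\].
#' @export
chance_novel <- function(x, interviewer,
                         item_class = c("species", "use", "plant_use"),
                         method = c("pool_fraction", "weighted_resample"),
                         n_rep = 199, seed = 1) {
  item_class <- match.arg(item_class)
  method <- match.arg(method)
  tbl <- tibble::as_tibble(x)
  all_incid <- dplyr::distinct(
    tibble::tibble(interview_id = tbl$interview_id[!is.na(tbl$species_id)],
                   item = items_of(tbl, item_class)))
  pool <- unique(all_incid$item)
  if (length(pool) == 0) abort("Empty study-wide item pool.")
  own <- interviewer_own_items(x, interviewer, item_class)
  if (method == "pool_fraction") {
    return(100 * (length(pool) - length(intersect(own, pool))) / length(pool))
  }
  stopifnot_scalar_count(n_rep, "n_rep")
  corpus <- tbl[tbl$interviewer_id == interviewer &
                tbl$informant_id != interviewer &
                !is.na(tbl$species_id), , drop = FALSE]
  elicited <- unique(items_of(corpus, item_class))
  if (length(elicited) == 0) {
    abort(sprintf("Interviewer `%s` elicited no items.", interviewer))
  }
  weights <- table(all_incid$item)[pool]
  size <- min(length(own), length(pool))
  reps <- with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      fake_own <- sample(pool, size, prob = as.numeric(weights))
      novel <- sum(!(elicited %in% fake_own))
      pct_novel(novel, length(elicited) - novel)
    }, numeric(1))
  })
  mean(reps)
}

#' Novelty table across interviewers and item classes
#'
#' [novelty_counts()] for every requested interviewer and item class, with
#' both chance baselines attached. Interviewers default to roster members
#' who have a self-interview and conducted at least one other interview.
#'
#' @inheritParams interviewer_own_items
#' @param interviewers Interviewer ids to tabulate (default: all eligible).
#' @param item_classes Item classes to tabulate.
#' @param n_rep,seed Monte-Carlo settings for the `weighted_resample`
#'   baseline; `n_rep = 0` skips it.
#' @return A tibble with one row per interviewer and item class, the
#'   novel/same unique and mention counts, `pct_novel_unique`, and
#'   `chance_pool_fraction` / `chance_weighted_resample` columns.
#' @export
novelty_table <- function(x, interviewers = NULL,
                          item_classes = c("species", "use", "plant_use"),
                          n_rep = 199, seed = 1) {
  tbl <- tibble::as_tibble(x)
  if (is.null(interviewers)) {
    selfs <- interviewer_self_rows(x)
    conducted <- unique(tbl$interviewer_id[tbl$informant_id !=
                                             tbl$interviewer_id])
    interviewers <- intersect(unique(selfs$interviewer_id), conducted)
  }
  if (!length(interviewers)) abort("No eligible interviewer for novelty.")
  grid <- tidyr::expand_grid(interviewer = interviewers,
                             item_class = item_classes)
  rows <- purrr::pmap(grid, function(interviewer, item_class) {
    row <- novelty_counts(x, interviewer, item_class)
    row$chance_pool_fraction <- chance_novel(x, interviewer, item_class,
                                             method = "pool_fraction")
    if (n_rep > 0) {
      row$chance_weighted_resample <- chance_novel(
        x, interviewer, item_class, method = "weighted_resample",
        n_rep = n_rep, seed = seed)
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Published reference novelty counts
#'
#' The per-interviewer novel/same counts (distinct items and mentions, per
#' item class) published for five interviewers of a whole-population
#' Chacobo plant-use freelist survey, shipped with the package. Feeding the
#' unique counts through [pct_novel()] reproduces the published novelty
#' percentage ranges.
#'
#' @return A tibble with columns `interviewer`, `group`, `item_class`,
#'   `status` (novel/same), `unique`, `mentions`.
#' @export
reference_novelty_counts <- function() {
  path <- system.file("extdata", "chacobo_novelty_counts.tsv",
                      package = "freelistr", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
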