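#' Build an interviews-by-items presence/absence matrix
#'
#' Turns an interview table into a 0/1 incidence matrix with one row per
#' interview and one column per distinct item. Items are defined by `mode`:
#' `"species"` (distinct species), `"use"` (use subcategories at
#' `level = "subcategory"`, major categories at `level = "major_category"`),
#' or `"plant_use"` (distinct pairs of species and major use category,
#' rendered as `species::major_category`). A cell is 1 iff the interview
#' contains at least one report mapping to that item.
#'
#' Interviews with no reports cannot enter Jaccard or Bray-Curtis
#' dissimilarities; they are dropped from the matrix with a warning and
#' recorded in the result.
#'
#' @param x An interview table (see [read_interviews()]).
#' @param mode Item definition: `"species"`, `"use"`, or `"plant_use"`.
#' @param level For `mode = "use"`, whether items are use subcategories or
#'   major categories. Ignored for the other modes (`plant_use` always pairs
#'   species with major category).
#' @return An object of class `incidence_matrix`: a list with elements
#'   `incidence` (integer 0/1 matrix, rownames = interview ids, colnames =
#'   item labels), `meta` (tibble of per-interview informant metadata aligned
#'   with the rows), `mode`, `level`, and `dropped` (ids of empty interviews
#'   excluded).
#' @export
build_incidence <- function(x, mode = c("species", "use", "plant_use"),
                            level = c("subcategory", "major_category")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  tbl <- tibble::as_tibble(x)
  if (nrow(tbl) == 0) abort("Interview table is empty.")

  meta <- interview_meta(x)
  reports <- tbl[!is.na(tbl$species_id), , drop = FALSE]
  item <- switch(mode,
    species = reports$species_id,
    use = if (level == "subcategory") reports$use_subcategory
          else reports$major_category,
    plant_use = paste(reports$species_id, reports$major_category, sep = "::")
  )
  reports$item <- item

  dropped <- setdiff(meta$interview_id, unique(reports$interview_id))
  if (length(dropped)) {
    warn(sprintf("Excluding %d interview(s) with no reports from incidence: %s.",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  meta <- meta[!meta$interview_id %in% dropped, , drop = FALSE]

  rows <- meta$interview_id
  cols <- sort(unique(reports$item))
  inc <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  inc[cbind(match(reports$interview_id, rows), match(reports$item, cols))] <- 1L

  structure(list(incidence = inc, meta = meta, mode = mode,
                 level = if (mode == "use") level else "major_category",
                 dropped = dropped),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d interviews x %d %s items (level: %s)\n",
              nrow(x$incidence), ncol(x$incidence), x$mode, x$level))
  if (length(x$dropped)) {
    cat(sprintf("  %d empty interview(s) excluded\n", length(x$dropped)))
  }
  invisible(x)
}

# long tibble of the 1-cells: one row per (interview, item) incidence,
# joined with informant metadata
#' @export
tidy.incidence_matrix <- function(x, ...) {
  ones <- which(x$incidence == 1L, arr.ind = TRUE)
  out <- tibble::tibble(
    interview_id = rownames(x$incidence)[ones[, 1]],
    item = colnames(x$incidence)[ones[, 2]]
  )
  out <- dplyr::left_join(out, x$meta, by = "interview_id")
  dplyr::arrange(out, .data$interview_id, .data$item)
}
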