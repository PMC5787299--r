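#' Read and normalize long-format interview records
#'
#' Reads one row per elicited species-use report from a delimited text file
#' (comma- or tab-separated, sniffed from the file extension) and returns a
#' normalized interview table: one row per distinct
#' (interview, species, use description) report, with interview-level
#' metadata repeated on every row. Duplicate reports within an interview are
#' collapsed to a single row (freelists record presence, not within-interview
#' repetition) and the number of collapsed rows is reported.
#'
#' Required columns (after applying `schema`): `interview_id`,
#' `informant_id`, `interviewer_id`, `species_id`, `use_description`,
#' `use_subcategory`, `major_category`. Optional: `gender`, `age_class`,
#' `ethnicity`, `date`. Rows with a missing `species_id` are kept as markers
#' of an interview that elicited no reports.
#'
#' @param path Path to a CSV or TSV file.
#' @param schema Optional named character vector remapping file column names,
#'   e.g. `c(interview_id = "IntID")` means the file column `IntID` holds the
#'   interview identifier.
#' @param categories Allowed major use categories; defaults to the seven
#'   labels of [major_categories()].
#' @param roster Optional character vector of interviewer identifiers. When
#'   supplied, an `interviewer_id` outside the roster is an error; when
#'   `NULL` the roster is inferred from the data.
#' @param quiet Suppress informational messages.
#' @return A tibble of class `interview_tbl` with attributes `roster`
#'   (interviewer roster), `categories`, and `n_collapsed` (count of
#'   within-interview duplicate rows removed).
#' @seealso [as_interview_tbl()] to normalize an in-memory data frame,
#'   [build_incidence()], [repeat_subset()], [interviewer_self_rows()].
#' @export
read_interviews <- function(path, schema = NULL,
                            categories = major_categories(),
                            roster = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  as_interview_tbl(raw, schema = schema, categories = categories,
                   roster = roster, quiet = quiet)
}

#' Normalize a data frame of interview records
#'
#' Applies the same schema mapping, validation, and within-interview
#' deduplication as [read_interviews()] to an in-memory data frame.
#'
#' @inheritParams read_interviews
#' @param x A data frame with one row per elicited report.
#' @return A tibble of class `interview_tbl`; see [read_interviews()].
#' @export
as_interview_tbl <- function(x, schema = NULL,
                             categories = major_categories(),
                             roster = NULL, quiet = FALSE) {
  x <- tibble::as_tibble(x)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      file_col <- schema[[std]]
      if (!file_col %in% names(x)) {
        abort(sprintf("Schema column `%s` (mapped to `%s`) not found in input.",
                      file_col, std))
      }
      names(x)[names(x) == file_col] <- std
    }
  }
  required <- c("interview_id", "informant_id", "interviewer_id",
                "species_id", "use_description", "use_subcategory",
                "major_category")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  optional <- c("gender", "age_class", "ethnicity", "date")
  for (col in setdiff(optional, names(x))) x[[col]] <- NA_character_
  x <- x[, c(required, optional)]

  label_cols <- c("interview_id", "informant_id", "interviewer_id",
                  "species_id", "use_subcategory", "major_category",
                  "gender", "age_class", "ethnicity")
  for (col in label_cols) x[[col]] <- trimws(as.character(x[[col]]))
  x$use_description <- trimws(as.character(x$use_description))
  x$species_id[!is.na(x$species_id) & x$species_id == ""] <- NA_character_

  # empty-interview markers: no species reported
  is_marker <- is.na(x$species_id)

  bad_cat <- !is_marker & !(x$major_category %in% categories)
  if (any(bad_cat)) {
    abort(sprintf(
      "Unknown major_category in %d row(s) (allowed: %s); first offending rows: %s.",
      sum(bad_cat), paste(categories, collapse = ", "),
      paste(head(which(bad_cat), 5), collapse = ", ")))
  }

  # one informant and interviewer per interview id
  per_int <- dplyr::distinct(x, .data$interview_id, .data$informant_id,
                             .data$interviewer_id)
  dup_int <- per_int$interview_id[duplicated(per_int$interview_id)]
  if (length(dup_int)) {
    abort(sprintf("Interview id(s) with inconsistent informant/interviewer: %s.",
                  paste(unique(dup_int), collapse = ", ")))
  }

  n_int <- table(per_int$informant_id)
  over <- names(n_int)[n_int > 2]
  if (length(over)) {
    abort(sprintf("Informant(s) with more than 2 interviews: %s.",
                  paste(over, collapse = ", ")))
  }

  if (!is.null(roster)) {
    stray <- setdiff(unique(x$interviewer_id), roster)
    if (length(stray)) {
      abort(sprintf("interviewer_id(s) not in declared roster: %s.",
                    paste(stray, collapse = ", ")))
    }
  } else {
    roster <- sort(unique(x$interviewer_id))
  }

  n_before <- nrow(x)
  x <- dplyr::distinct(x, .data$interview_id, .data$species_id,
                       .data$use_description, .keep_all = TRUE)
  n_collapsed <- n_before - nrow(x)
  if (n_collapsed > 0 && !quiet) {
    inform(sprintf("Collapsed %d duplicate within-interview report(s).",
                   n_collapsed))
  }
  if (!quiet && length(categories) != 7L) {
    inform(sprintf("Using a %d-label major-category set.", length(categories)))
  }

  x <- dplyr::arrange(x, .data$interview_id, .data$species_id,
                      .data$use_description)
  structure(x,
            class = c("interview_tbl", class(tibble::tibble()))) |>
    `attr<-`("roster", roster) |>
    `attr<-`("categories", categories) |>
    `attr<-`("n_collapsed", n_collapsed)
}

#' Write an interview table back to delimited text
#'
#' @param x An interview table (or any data frame of interview records).
#' @param path Output path; `.tsv` writes tab-separated, anything else
#'   comma-separated.
#' @return `path`, invisibly.
#' @export
write_interviews <- function(x, path) {
  delim <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(tibble::as_tibble(x), path, delim = delim, na = "")
  invisible(path)
}

# interviewer roster of a table (attribute if present, else inferred)
interviewer_roster <- function(x) {
  attr(x, "roster") %||% sort(unique(x$interviewer_id))
}

#' Interview-level metadata
#'
#' One row per interview: identifiers and informant demographics, plus the
#' count of distinct reports in the interview (0 for empty-interview
#' markers).
#'
#' @param x An interview table.
#' @return A tibble with columns `interview_id`, `informant_id`,
#'   `interviewer_id`, `gender`, `age_class`, `ethnicity`, `date`,
#'   `n_reports`.
#' @export
interview_meta <- function(x) {
  x <- tibble::as_tibble(x)
  x |>
    dplyr::group_by(.data$interview_id, .data$informant_id,
                    .data$interviewer_id, .data$gender, .data$age_class,
                    .data$ethnicity, .data$date) |>
    dplyr::summarise(n_reports = sum(!is.na(.data$species_id)),
                     .groups = "drop") |>
    dplyr::arrange(.data$interview_id)
}

#' Informants interviewed twice
#'
#' Identifies the repeat-interview subset: informants with exactly two
#' interviews, conducted by two distinct interviewers. Within a pair,
#' interviews are ordered by `date` when available and by `interview_id`
#' otherwise.
#'
#' @param x An interview table.
#' @return A tibble with columns `informant_id`, `interview_1`,
#'   `interview_2`, `interviewer_1`, `interviewer_2`; zero rows when no
#'   informant was interviewed twice.
#' @export
repeat_subset <- function(x) {
  meta <- interview_meta(x)
  twice <- meta |>
    dplyr::count(.data$informant_id) |>
    dplyr::filter(.data$n == 2L)
  if (nrow(twice) == 0) {
    return(tibble::tibble(informant_id = character(), interview_1 = character(),
                          interview_2 = character(), interviewer_1 = character(),
                          interviewer_2 = character()))
  }
  pairs <- meta |>
    dplyr::filter(.data$informant_id %in% twice$informant_id) |>
    dplyr::group_by(.data$informant_id) |>
    dplyr::arrange(ifelse(is.na(.data$date), .data$interview_id, .data$date),
                   .data$interview_id, .by_group = TRUE) |>
    dplyr::summarise(interview_1 = .data$interview_id[1],
                     interview_2 = .data$interview_id[2],
                     interviewer_1 = .data$interviewer_id[1],
                     interviewer_2 = .data$interviewer_id[2],
                     .groups = "drop")
  same <- pairs$interviewer_1 == pairs$interviewer_2
  if (any(same)) {
    warn(sprintf(
      "Dropping %d informant(s) interviewed twice by the same interviewer: %s.",
      sum(same), paste(pairs$informant_id[same], collapse = ", ")))
    pairs <- pairs[!same, , drop = FALSE]
  }
  dplyr::arrange(pairs, .data$informant_id)
}

#' Interviews in which an interviewer was the informant
#'
#' For each member of the interviewer roster who also appears as an
#' informant, returns their interview(s)-as-informant. When an interviewer
#' was interviewed twice, both interviews are returned; downstream consumers
#' that need a single "own answers" interview prefer the one conducted by a
#' different interviewer (see [pull_statistic()]).
#'
#' @param x An interview table.
#' @return A tibble with columns `interviewer_id` (the roster member),
#'   `interview_id` (their interview as informant), and `conducted_by`.
#' @export
interviewer_self_rows <- function(x) {
  roster <- interviewer_roster(x)
  meta <- interview_meta(x)
  meta |>
    dplyr::filter(.data$informant_id %in% roster) |>
    dplyr::transmute(conducted_by = .data$interviewer_id,
                     interviewer_id = .data$informant_id,
                     interview_id = .data$interview_id) |>
    dplyr::select("interviewer_id", "interview_id", "conducted_by") |>
    dplyr::arrange(.data$interviewer_id, .data$interview_id)
}

# single "own answers" interview per interviewer: if interviewed twice,
# prefer the interview conducted by someone else (least self-influenced)
self_interview_of <- function(x, interviewer) {
  selfs <- interviewer_self_rows(x)
  mine <- selfs[selfs$interviewer_id == interviewer, , drop = FALSE]
  if (nrow(mine) == 0) return(NA_character_)
  other <- mine[mine$conducted_by != interviewer, , drop = FALSE]
  if (nrow(other)) other$interview_id[1] else mine$interview_id[1]
}
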