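#' Run the full interviewer-effect pipeline
#'
#' Orchestrates the analysis end to end from a single configuration:
#' read (or simulate) interviews, build incidence matrices, compute
#' dissimilarities, ordinate, fit factors, compute interviewer effects and
#' intra/inter distances, and tabulate novelty — writing each stage's
#' TSV/JSON artifact into `outdir` together with a `MANIFEST.tsv` listing
#' every file with its MD5 checksum. Identical configuration and seed give
#' byte-identical numeric artifacts. A stage failure aborts with a message
#' naming the stage; artifacts written so far are kept and the manifest is
#' marked incomplete.
#'
#' @param input Path to a CSV/TSV of interview records, or a scenario name
#'   (`"null"`, `"pull"`, `"tighten"`, `"paper_like"`) to simulate.
#' @param outdir Output directory (created if missing).
#' @param item_classes Incidence modes to analyse.
#' @param metric Dissimilarity metric (see [pairwise_dissimilarity()]).
#' @param k,n_restarts NMDS dimensions and restarts.
#' @param n_perm Permutations for factor fits and effect tests.
#' @param seed Master seed; item class `c` ordinates with `seed + 100*c`.
#' @param stages Which stages to run; `"ordinate"` is implied by any stage
#'   that needs coordinates.
#' @param schema Optional column remapping passed to [read_interviews()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stage results and the manifest
#'   tibble.
#' @export
run_pipeline <- function(input, outdir,
                         item_classes = c("species", "use", "plant_use"),
                         metric = "jaccard", k = 2, n_restarts = 10,
                         n_perm = 999, seed = 1,
                         stages = c("incidence", "ordinate", "factors",
                                    "effects", "novelty"),
                         schema = NULL, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!length(stages)) abort("At least one stage must be enabled.")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  results <- list()
  say <- function(...) if (!quiet) inform(sprintf(...))
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      readr::write_tsv(tibble::as_tibble(x), path)
    }
    files <<- c(files, path)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest(status = sprintf("INCOMPLETE (failed in stage %s)", name))
      abort(sprintf("Stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  manifest <- function(status = "complete") {
    mf <- tibble::tibble(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
    cfg_hash <- rlang::hash(list(input = input, item_classes = item_classes,
                                 metric = metric, k = k,
                                 n_restarts = n_restarts, n_perm = n_perm,
                                 seed = seed, stages = stages))
    header <- sprintf("# status: %s | config: %s | seed: %d",
                      status, cfg_hash, seed)
    path <- file.path(outdir, "MANIFEST.tsv")
    writeLines(c(header, paste(names(mf), collapse = "\t"),
                 apply(mf, 1, paste, collapse = "\t")), path)
    mf
  }

  tbl <- stage("input", {
    if (input %in% c("null", "pull", "tighten", "paper_like")) {
      say("Simulating scenario `%s` (seed %d)", input, seed)
      sc <- scenario(input, seed)
      emit(tibble::as_tibble(sc$table), "interviews.tsv")
      sc$table
    } else {
      say("Reading interviews from %s", input)
      read_interviews(input, schema = schema, quiet = quiet)
    }
  })
  results$table <- tbl

  need_ord <- any(c("ordinate", "factors", "effects") %in% stages)
  for (ci in seq_along(item_classes)) {
    cls <- item_classes[ci]
    class_seed <- seed + 100 * ci
    if (!need_ord && !"incidence" %in% stages) break
    inc <- stage(paste0("incidence[", cls, "]"), {
      m <- suppressWarnings(build_incidence(tbl, mode = cls))
      out <- tibble::as_tibble(m$incidence, rownames = "interview_id")
      emit(out, sprintf("incidence_%s.tsv", cls))
      m
    })
    if (!need_ord) next
    d <- stage(paste0("dissimilarity[", cls, "]"),
               pairwise_dissimilarity(inc, metric))
    ord <- stage(paste0("ordinate[", cls, "]"), {
      say("NMDS on %d interviews (%s)", attr(d, "Size"), cls)
      o <- suppressWarnings(nmds(d, k = k, n_restarts = n_restarts,
                                 seed = class_seed))
      emit(tidy(o), sprintf("ordination_%s.tsv", cls))
      emit(as.list(glance(o)), sprintf("ordination_%s.json", cls))
      o
    })
    results[[cls]]$ordination <- ord
    if ("factors" %in% stages) {
      results[[cls]]$factors <- stage(paste0("factors[", cls, "]"), {
        ft <- suppressWarnings(fit_all(ord, tbl, n_perm = n_perm,
                                       seed = class_seed))
        emit(ft, sprintf("factor_fits_%s.tsv", cls))
        ft
      })
    }
    if ("effects" %in% stages) {
      results[[cls]]$effects <- stage(paste0("effects[", cls, "]"), {
        ef <- suppressWarnings(interviewer_effects(ord, tbl, n_perm = n_perm,
                                                   seed = class_seed))
        emit(ef, sprintf("interviewer_effects_%s.tsv", cls))
        ii <- suppressWarnings(intra_inter(ord, tbl, n_perm = n_perm,
                                           seed = class_seed))
        emit(tidy(ii), sprintf("intra_distances_%s.tsv", cls))
        emit(glance(ii), sprintf("intra_inter_%s.tsv", cls))
        list(effects = ef, intra_inter = ii)
      })
    }
  }

  if ("novelty" %in% stages) {
    results$novelty <- stage("novelty", {
      nv <- novelty_table(tbl, item_classes = item_classes, seed = seed)
      emit(nv, "novelty.tsv")
      nv
    })
  }

  results$manifest <- manifest()
  say("Wrote %d artifact(s) to %s", length(files) + 1, outdir)
  invisible(results)
}
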