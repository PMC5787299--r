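# in-code fixtures shared across test files

# compact constructor for long-format interview rows
rec <- function(interview, informant, interviewer, species, use,
                subcat = "fever-remedy", major = "medical",
                gender = "female", age = "31-40", ethnicity = "chacobo") {
  tibble::tibble(interview_id = interview, informant_id = informant,
                 interviewer_id = interviewer, species_id = species,
                 use_description = use, use_subcategory = subcat,
                 major_category = major, gender = gender, age_class = age,
                 ethnicity = ethnicity)
}

tbl_of <- function(..., roster = NULL) {
  as_interview_tbl(dplyr::bind_rows(...), roster = roster, quiet = TRUE)
}

# random small freelist table: n interviews over a pool of items, each
# interview a random subset; informants single-interview
random_table <- function(n_interviews = 10, n_species = 12, seed = 1,
                         n_interviewers = 2) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_interviews), function(i) {
      sp <- sample(sprintf("sp%02d", seq_len(n_species)),
                   sample(2:6, 1))
      major <- sample(major_categories(), length(sp), replace = TRUE)
      rec(sprintf("I%02d", i), sprintf("P%02d", i),
          sprintf("J%d", 1 + (i %% n_interviewers)),
          sp, paste("use of", sp, "as", major), subcat = paste0("s_", major),
          major = major)
    })
    tbl_of(rows)
  })
}

# planted two-cluster coordinates with labels, for factor fits
two_cluster_coords <- function() {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(X) <- paste0("I", 1:4)
  list(coords = X, labels = c("A", "A", "B", "B"))
}

# four repeat informants with hand-placed coordinates; J1's own-elicited
# interviews at ya, other-elicited at yb; J1 self-interview at self_pt
effects_fixture <- function(own = rbind(c(1, 0), c(3, 0)),
                            other = rbind(c(0, 0), c(0, 2)),
                            self_pt = NULL) {
  m <- nrow(own)
  rows <- list()
  coords <- NULL
  ids <- character()
  for (i in seq_len(m)) {
    ido <- sprintf("A%d", i)
    idx <- sprintf("B%d", i)
    p <- sprintf("R%d", i)
    rows[[length(rows) + 1]] <- rec(ido, p, "J1", "sp1", "u1")
    rows[[length(rows) + 1]] <- rec(idx, p, "J2", "sp2", "u2")
    coords <- rbind(coords, own[i, ], other[i, ])
    ids <- c(ids, ido, idx)
  }
  if (!is.null(self_pt)) {
    rows[[length(rows) + 1]] <- rec("SELF1", "J1", "J2", "sp3", "u3")
    coords <- rbind(coords, self_pt)
    ids <- c(ids, "SELF1")
    rows[[length(rows) + 1]] <- rec("SELF2", "J2", "J1", "sp4", "u4")
    coords <- rbind(coords, c(50, 50))
    ids <- c(ids, "SELF2")
  }
  rownames(coords) <- ids
  list(table = tbl_of(rows, roster = c("J1", "J2")), coords = coords)
}
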