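# freelistr

Quantifying interviewer effects in freelist surveys of traditional
ecological knowledge.

When a whole community's plant knowledge is inventoried by many
interviewers — each freelisting participant reporting the species and uses
they recall — the interviewer becomes part of the measurement. freelistr
implements the analysis chain for asking how much that matters:

* **Ordination of interviews.** Presence/absence incidence matrices over
  species, use subcategories, or plant–use combinations; Jaccard (or
  Sørensen) dissimilarities; non-metric multidimensional scaling
  minimizing Kruskal's stress-1 (pool-adjacent-violators monotone
  regression inside a majorization loop, with restarts, a monotone stress
  trace, and Procrustes utilities for comparing configurations).
* **Factor fits.** For interviewer identity and informant demographics,
  `r² = 1 − SS_within/SS_total` on ordination scores with permutation
  significance.
* **Interviewer effects on the repeat subset.** For informants
  interviewed twice by different interviewers: per-interviewer effect
  vectors (centroid of interviewer-elicited minus other-elicited
  interviews), *pull* (does an interviewer elicit answers close to their
  own knowledge?), *tighten* (are their elicited answer sets closer to
  one another?), within-pair swap permutation tests, and intra- versus
  inter-informant distances.
* **Novelty accounting.** Per interviewer and item class, how much of
  what they elicited was absent from their own recorded knowledge, with
  two explicit chance baselines.
* **A generative simulator** of the elicitation process (Rasch-style
  knowledge model + logistic reporting with tunable interviewer bias and
  probe-list narrowing), with full ground truth, used for the packaged
  calibration and recovery studies.

## Worked example

Simulate a survey with a known pull bias, ordinate it, and ask whether
interviewer identity structures the answers:

```r
library(freelistr)

sc  <- scenario("pull", seed = 1)          # 150 informants, 6 interviewers, beta = 1.5
inc <- build_incidence(sc$table, mode = "plant_use")
d   <- pairwise_dissimilarity(inc, "jaccard")
ord <- nmds(d, k = 2, n_restarts = 10, seed = 1)
glance(ord)
#> # A tibble: 1 x 7
#>   stress     k     n n_restarts best_restart iterations converged
#>    <dbl> <dbl> <int>      <dbl>        <int>      <dbl> <lgl>
#> 1  0.313     2   195         10            6        500 FALSE

fit_all(ord, sc$table, n_perm = 999, seed = 1)
#> # A tibble: 4 x 5
#>   factor               r2 p_value n_perm  seed
#>   <chr>             <dbl>   <dbl>  <int> <int>
#> 1 interviewer_id 0.0811     0.001    999     1
#> 2 gender         0.000151   0.973    999     2
#> 3 age_class      0.0269     0.231    999     3
#> 4 ethnicity      0.00509    0.347    999     4
```

Interviewer identity explains three times the ordination variance of any
demographic factor and is the only factor the permutation test flags
(p = 0.001) — the ordering the method is designed to expose. (The stress
warning at 500 iterations is typical for noisy survey-sized data; the
embedding is still usable, and `nmds()` never hides non-convergence.) The
pull statistic on the repeat-interview subset, measured on the raw
dissimilarities, recovers the planted bias interviewer by interviewer:

```r
pull_tbl <- lapply(attr(sc$table, "roster"), function(j) {
  ps <- pull_statistic(NULL, sc$table, j, space = "dissimilarity", d = d)
  ps$p_value <- effect_significance(NULL, sc$table, j, "pull",
                                    n_perm = 999, seed = 1,
                                    space = "dissimilarity", d = d)$p_value
  ps
}) |> dplyr::bind_rows()
dplyr::select(pull_tbl, interviewer_id, n_pairs, pull, p_value)
#> # A tibble: 6 x 4
#>   interviewer_id n_pairs    pull p_value
#>   <chr>            <int>   <dbl>   <dbl>
#> 1 P001                13 0.0560    0.017
#> 2 P020                20 0.0235    0.098
#> 3 P110                 8 0.0518    0.077
#> 4 P120                16 0.0419    0.011
#> 5 P129                19 0.00158   0.482
#> 6 P140                14 0.00434   0.393
```

Every interviewer elicits answers closer to their own knowledge than the
same informants gave to others (positive `pull`), clearly so for some and
within noise for others — the heterogeneity real multi-interviewer
surveys show. `interviewer_effects()` assembles the full per-interviewer
table (effect vectors, pull, tighten, permutation p-values) in ordination
space, and `novelty_table()` completes the picture: even pulled answers
are mostly items the interviewer did not report themselves — the
published counts shipped in `reference_novelty_counts()` imply 60-84%
novelty depending on item class.

`run_pipeline("pull", "out/", seed = 1)` executes the whole chain and
writes TSV/JSON artifacts plus a checksummed manifest;
`autoplot(ord, sc$table, facet = TRUE)` and `plot_effect_vectors()`
reproduce the standard displays. The methods vignette
(`vignettes/interviewer-effects.Rmd`) documents the models, the
simulator, and every numerical design choice.

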