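# screenrec

Drug-response recommendation for patient-derived cell cultures from a
small probing panel plus historical screening data.

## The problem

Ex vivo drug screening — exposing cells cultured from a patient biopsy to
a drug library and measuring the response — is one of the most direct
routes to personalised cancer therapy, but screening a full library
(hundreds to thousands of compounds) on every fresh culture is slow and
expensive. `screenrec` implements a recommender system that needs only a
small **probing panel** (tens of drugs) measured on the new culture. Using
a historical cell-line × drug response matrix, it learns how the new
culture relates to previously screened cell lines and predicts its
response to every remaining library drug, ranking the library best-first.

The model transposes the usual supervised layout: **drugs are the samples
and historical cell lines are the features**. Each panel drug contributes
a training row (its activities across the historical cells; target = the
new culture's measured activity for that drug); a random forest (50 trees,
default parameters) then predicts every other library drug. Because
features are cell lines, the forest's feature importances identify the
most informative historical cultures and their tissues of origin.

Three dataset families are supported through activity schemes:
pIC50 screens (`log10(1/IC50)`, hit if > 6, i.e. IC50 ≤ 1 µM),
inverse log2 fold-change screens (hit if > 1.7), and % viability screens
(hit if ≤ 30% of DMSO control). The package covers the full pipeline:

* matrix ingestion/pruning/transforms (`read_response_matrix()`,
  `prune_matrix()`, `transform_targets()`, `call_hits()`,
  `selective_drugs()`);
* zero-fill and TML (per-drug boosted-stump) imputation (`impute_zero()`,
  `impute_tml()`), with held-out cell lines provably untouched;
* probing-panel selection by a variance + median-correlation greedy
  diversity algorithm or random sampling (`select_diverse()`,
  `fit_panel_to_size()`, `select_random()`);
* the recommender itself (`recommend_drugs()`, `fit_and_rank()`,
  `tissue_composition()`);
* the metric battery (top-n overlap, top-k hit rate with headroom,
  correlations/RMSE; `evaluate_recommendation()`);
* repeated 80/10/10 hold-out and leave-one-out experiment protocols
  (`run_holdout()`, `run_leave_one_out()`);
* a low-rank synthetic screen generator with tissue clusters and known
  ground truth (`simulate_screen()`, `make_biopsy_screen()`).

Results are tibbles throughout, with `tidy()`, `glance()` and `autoplot()`
methods on every fitted object.

## Worked example

Simulate a dense screen, hold out a test culture, build a 30-drug probing
panel and recommend from it:

```r
library(screenrec)

scr <- simulate_screen(n_cells = 300, n_drugs = 120, seed = 1)
m <- scr$matrix

split <- split_dataset(m, seed = 1)
train <- m[split$train, ]
completed <- impute_tml(train, seed = 1)
panel <- fit_panel_to_size(train, "drugs", target_size = 30)
cohort <- select_random(train, "cells", 100, seed = 1)

new_cell <- split$test[1]
profile <- m$values[new_cell, panel]
profile <- profile[!is.na(profile)]   # panel drugs actually measured
rec <- recommend_drugs(completed, names(profile), profile,
                       historical_cells = cohort, new_cell_id = new_cell,
                       seed = 1)
rec
#> <recommendation> for 'cell_081': 92 drugs ranked, 22 predicted hits (random_forest, 50 trees)
#> # A tibble: 5 x 4
#>   drug_id  predicted  rank predicted_hit
#>   <chr>        <dbl> <int> <lgl>
#> 1 drug_053      7.99     1 TRUE
#> 2 drug_050      7.92     2 TRUE
#> 3 drug_052      7.73     3 TRUE
#> 4 drug_048      7.70     4 TRUE
#> 5 drug_094      7.50     5 TRUE
```

The top of the ranking is the per-culture shortlist: predicted pIC50
activities with the `> 6` hit flag applied. Scoring against the culture's
held-back measurements:

```r
evaluate_recommendation(rec, m$values[new_cell, ],
                        selective = selective_drugs(call_hits(train)))
#>            subset n_drugs r_pearson r_spearman  rmse top_10 n_hits_topk n_hits_available
#> 1       all_drugs      79     0.969      0.974 0.440    0.8          10               17
#> 2 selective_drugs      57     0.963      0.969 0.402    0.9          10               12
```

Here 8 of the 10 best-predicted drugs are among the 10 actually best
(`top_10 = 0.8`), and all 10 top predictions are true hits
(`n_hits_topk = 10` of 17 available). The influential historical cultures
lean towards the new culture's tissue cluster:

```r
tissue_composition(rec, scr$annotations, top_k = 10)
#> # A tibble: 4 x 2
#>   tissue        n
#> 1 tissue_02     5
#> 2 tissue_01     2
#> 3 tissue_03     2
#> 4 tissue_04     1
```

For full experiment designs use `run_holdout()` (repeated 80/10/10
hold-out with per-repeat panel selection and imputation) or
`run_leave_one_out()` (small post-biopsy viability screens). The methods
vignette (`vignettes/drug-response-recommendation.Rmd`) documents the
model, the selection algorithm's tie-breaking, the generator's
assumptions and the package's limitations.

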