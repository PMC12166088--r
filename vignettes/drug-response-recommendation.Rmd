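---
title: "Recommending drugs for patient-derived cell cultures from probing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending drugs for patient-derived cell cultures from probing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenrec)
library(dplyr)
```

## The problem

Functional precision oncology screens a library of drugs directly against
cells cultured from a patient's tumour and treats the measured responses as
the treatment-relevant readout. Screening a full library (hundreds to
thousands of compounds) on every fresh culture is expensive and slow, and
fresh biopsies yield limited material. `screenrec` implements a
*recommender* shortcut: screen only a small **probing panel** of drugs on
the new culture, then use a historical cell-line × drug response matrix to
predict the culture's response to every remaining library drug, and rank
the library best-first.

The statistical bet is that drug-response profiles across cell lines are
highly redundant — a low-dimensional structure shared across tissues — so
a new culture's position in that structure can be located from a few dozen
well-chosen probes.

## The model

Everything revolves around a cell-line × drug activity matrix. Three
**activity schemes** fix the scale, the hit rule, and which direction is
"better":

| scheme | activity value | hit rule | ranking |
|---|---|---|---|
| `gdsc_pIC50` | `log10(1 / IC50[M])` | activity > 6 (IC50 ≤ 1 µM) | larger better |
| `prism_neglog2fc` | `-log2(fold change)` | activity > 1.7 | larger better |
| `viability_percent` | % of DMSO control | viability ≤ 30 | smaller better |

The hit boundaries are deliberately asymmetric: the log-activity rules are
strict (`> 6`, `> 1.7`) while the viability rule includes its boundary
(`≤ 30`), so a culture at exactly 30% viability counts as responsive.

For one new cell line the learning problem is transposed relative to the
usual supervised set-up: **drugs are the samples and historical cell lines
are the features**. Each probing-panel drug contributes one training row —
its activity across the historical cells — with the new line's measured
activity as the target; each remaining library drug is a prediction row.
A random forest (50 trees, library defaults) regresses the target from the
features; its per-feature importances therefore attach to historical
*cell lines*, which is what lets `tissue_composition()` ask whether
prediction leans on same-tissue cultures. A gradient-boosting learner is
available as an alternative.

Because the features are measured bioactivities rather than structural
descriptors, this is a transformational-machine-learning (TML) view of the
screen: other tasks' measurements serve as the representation.

## Pre-processing

`prune_matrix()` removes sparsely measured cell lines *first*, then drugs
that are missing in too many of the *remaining* cell lines. The order
matters and is fixed; the limits are fractional (e.g. 0.2/0.2 for dense
IC50 screens, 0.1/0.2 for large fold-change screens) or absolute counts
(5/5 for small viability panels). `transform_targets()` moves raw values
onto the activity scale and rejects non-positive IC50s or fold changes
with their location.

Two imputation routes complete a training matrix:

* `impute_zero()` — missing entries become 0 on the activity scale.
* `impute_tml()` — per-drug boosted regression stumps (gradient boosting,
  50 rounds, depth 1, shrinkage 0.1, no leaf penalty, initialised at the
  target mean). For each drug with gaps, the features are all other drugs
  with fewer than 20 missing entries among eligible cells (those gaps
  zero-filled), training cells are those where the drug was observed, and
  each drug is imputed independently from the original matrix — imputed
  columns are never chained. Held-out cell lines are excluded outright:
  they are neither read nor filled, which the test suite enforces by
  poisoning their rows and asserting bit-identical output elsewhere.

Each drug's booster is seeded from a hash of the global seed and the drug
id, and its feature columns are ordered lexicographically, so neither
column order nor row subsetting of other drugs changes a drug's imputed
values.

## Panel selection

`select_diverse()` implements a greedy redundancy filter: drop the
lowest-variance half of the candidates, rank survivors by median pairwise
Pearson correlation (ascending), then walk the ranking taking each
still-alive entity as a reference and knocking out everything that
correlates with it at or above a user threshold. The references, in
processing order, are the panel.

Three numerical choices were genuinely open and are fixed as follows:

* **Boundary of the exclusion rule.** Exclusion triggers at `r >=
  threshold` rather than strictly above. At any threshold ≤ 1 this makes
  perfect duplicates mutually exclusive (exactly one of an identical pair
  survives), and it gives the clean guarantee that every *selected* pair
  correlates strictly below the threshold.
* **Ties** in variance and in median correlation are broken by
  lexicographic id, making the output invariant to input row/column order.
* **Degenerate correlations** — a zero-variance side, or fewer than 3
  common observations in pairwise-complete data — are set to 0 rather
  than propagated as `NA`.

The threshold controls redundancy, not size. `fit_panel_to_size()` bisects
the threshold until at least the requested panel size is returned, then
truncates in processing order; when duplicates make the size unreachable it
returns the maximum achievable with a warning. `select_random()` is the
seeded uniform alternative used for historical-cohort sampling.

## Evaluation

Per cell line, `evaluate_recommendation()` reports Pearson and Spearman
correlation and RMSE of predicted vs measured activity, the top-n set
overlaps (n = 10, 20, 30 by default: the fraction of the n best-predicted
drugs that are among the n actually best), and the top-k hit rate (true
hits among the k best-predicted drugs, k = 10). All metrics are computed on
non-panel drugs with a measured response only — panel responses are inputs,
not predictions. Rank ties are broken by drug id on both the predicted and
the measured side, so metrics are deterministic. Hit metrics carry their
headroom: a cell line with only 3 hits available cannot exceed 3 hits in
any top 10, so the report includes `max_possible` and `frac_of_max`, and
flags cell lines with no hits at all as non-evaluable. "Selective" drugs —
active in strictly fewer than 20% of the training cell lines — get a
parallel set of metrics, since they are the harder and clinically more
interesting targets.

## Experiment protocols

`run_holdout()` is the main design: split cell lines 80/10/10 into
training/validation/test (largest-remainder rounding; 809 cells give a
647/81/81 split), impute the training matrix with validation and test cells
excluded, select the probing panel and a random historical cohort
(default 100 cells) on the training set, then recommend and score every
test cell line from its panel measurements alone. The whole procedure is
repeated (default 5 experiments), re-drawing the split each repeat with
seed `seed_base + repeat - 1`; summaries are the mean/sd across repeats of
per-repeat means. Hit metrics are reported both over all test cells and
restricted to evaluable ones.

`run_leave_one_out()` is the design for small, near-complete viability
screens where no cells can be spared for a hold-out: for each cell line,
each measured drug is predicted from the line's *other* measured drugs (its
panel) plus all other cell lines, and the per-drug predictions are
reassembled into a full predicted profile. The report mirrors the natural
summary for such screens: Spearman correlation, mean measured viability of
the library and of the top-5 predicted drugs, and hits
available/predicted/identified per cell line, with predicted hits defined
by the same ≤ 30% threshold as measured ones.

## The synthetic screen generator

`simulate_screen()` produces screens with known ground truth so the whole
pipeline is testable without downloads. Cell factors are drawn around
tissue-cluster means (`cluster_strength` sets the within-cluster shared
variance), drug factors are independent normals, and the rank-`r` product
is scaled to `activity_sd` and shifted so the realised hit prevalence
matches a target; Gaussian noise and uniform missing-at-random masking
follow. The affine calibration is folded into the stored factors, so the
noiseless truth is exactly `cell_factors %*% t(drug_factors)` (viability
surfaces are additionally clamped at 0, which cannot flip a hit call).

Default conditions are chosen once to emulate a dense IC50 screen: 800
cells × 300 drugs, latent rank 3, 5 tissue clusters, cluster strength 0.5,
activity sd 1.5 on the pIC50 scale, noise sd 0.3, 10% missingness, 17.8%
hit prevalence. `make_biopsy_screen()` is the small-screen counterpart: 24 cell
lines × 35 drugs on the viability scale, ~4.4 hits per cell line, and a
sparse missingness pattern capped at 5 gaps per cell line and per drug so
it survives absolute 5/5 pruning unchanged.

What the generator does **not** emulate: real viability distributions are
strongly right-skewed (most drugs leave viability near 100% of control),
while the Gaussian low-rank surface is symmetric — so the synthetic
library-mean viability (~55–65%) sits well below what a real post-biopsy
screen shows, even at matched hit prevalence. Real screens also have
block missingness (whole plates or drug sets untested), dose-response
artefacts and batch effects, none of which are modelled. Passing tests on
these screens therefore demonstrate that the machinery recovers planted
low-rank structure under noise and missingness at calibrated prevalence —
not that real-data performance will match.

## A worked example

```{r example, eval = FALSE}
scr <- simulate_screen(n_cells = 300, n_drugs = 120, seed = 1)
m <- scr$matrix

split <- split_dataset(m, seed = 1)
train <- m[split$train, ]
completed <- impute_tml(train, seed = 1)
panel <- fit_panel_to_size(train, "drugs", target_size = 30)
cohort <- select_random(train, "cells", 100, seed = 1)

new_cell <- split$test[1]
profile <- m$values[new_cell, panel]
profile <- profile[!is.na(profile)]  # panel drugs actually measured
rec <- recommend_drugs(completed, names(profile), profile,
                       historical_cells = cohort, new_cell_id = new_cell,
                       seed = 1)
tidy(rec)
evaluate_recommendation(rec, m$values[new_cell, ],
                        selective = selective_drugs(call_hits(train)))
tissue_composition(rec, scr$annotations, top_k = 10)
autoplot(rec)
```

For the full designs use `run_holdout()` / `run_leave_one_out()` with
`tidy()`, `glance()` and `autoplot()` on the returned reports.

## Problem sizes and numerical notes

The shipped evaluation (`scripts/acceptance.R` and the end-to-end tests)
runs the hold-out design at 300 cells × 300 drugs with 5 repeats and the
leave-one-out design at 24 × 35 with 5 repeats — sizes chosen so a full
replication of the package's own results completes in a couple of minutes
on one core while keeping ~30 test cell lines per repeat, enough for stable
per-repeat means.

Degenerate inputs are handled explicitly rather than by accident: constant
training targets fit and predict the constant but flag the ranking
low-confidence; a drug with no observed values falls back to zero-fill
with a warning; cell lines with fewer than 3 measured drugs are skipped in
leave-one-out; zero-variance correlation pairs count as uncorrelated;
empty pruning results raise errors instead of returning 0-dimensional
matrices.

## Limitations

* Predictions inherit a tree ensemble's range restriction: a new culture
  more extreme than anything spanned by its panel targets cannot be
  extrapolated to.
* The recommender assumes the probing panel was *measured* on the new
  culture; unmeasured panel drugs are dropped per cell with a warning,
  shrinking the training set.
* Cell-based activity transfers poorly to drug classes acting through the
  microenvironment or immune system (e.g. immunomodulators); nothing in
  the model corrects for that.
* Hit thresholds are fixed per scheme; calibrating them per dataset is out
  of scope.
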