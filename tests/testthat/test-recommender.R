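make_historical <- function(n_cells = 12, n_drugs = 10, seed = 1) {
  random_activity_matrix(n_cells, n_drugs, missing = 0, seed = seed)
}

test_that("the training table flips drugs to samples and cells to features", {
  hist <- make_historical()
  panel <- drug_ids(hist)[1:4]
  profile <- stats::setNames(rnorm(4, 5), panel)
  tbl <- build_training_table(hist, panel, profile, new_cell_id = "new1")
  expect_equal(dim(tbl$x_train), c(4, 12))      # panel drugs x cells
  expect_equal(dim(tbl$x_predict), c(6, 12))    # library drugs x cells
  expect_identical(rownames(tbl$x_train), panel)
  expect_identical(colnames(tbl$x_train), cell_ids(hist))
  expect_identical(tbl$x_train["d02", "c05"], hist$values["c05", "d02"])
  expect_equal(length(tbl$library_drugs), 6)

  # errors: unknown panel drug, historical overlap, incomplete matrix
  expect_error(build_training_table(hist, c(panel, "nope"), profile),
               "absent")
  expect_error(build_training_table(hist, panel, profile,
                                    new_cell_id = "c01"), "leakage")
  holey <- hist$values; holey[1, 5] <- NA
  expect_error(
    build_training_table(response_matrix(holey, hist$scheme,
                                         transformed = TRUE),
                         panel, profile),
    "impute")
  expect_warning(build_training_table(hist, panel[1], profile[1]),
                 "Single-drug")
})

test_that("non-panel measurements of the new cell line are never read", {
  hist <- make_historical(seed = 4)
  panel <- drug_ids(hist)[1:5]
  profile <- stats::setNames(rnorm(10, 5), drug_ids(hist))
  base <- suppressWarnings(
    recommend_drugs(hist, panel, profile, new_cell_id = "nx", seed = 7))
  poisoned <- profile
  poisoned[setdiff(names(profile), panel)] <- 1e9
  again <- suppressWarnings(
    recommend_drugs(hist, panel, poisoned, new_cell_id = "nx", seed = 7))
  expect_identical(base$predictions, again$predictions)
  expect_identical(base$importances, again$importances)
})

test_that("constant targets give constant predictions flagged low-confidence", {
  hist <- make_historical(seed = 5)
  panel <- drug_ids(hist)[1:4]
  profile <- stats::setNames(rep(5.5, 4), panel)
  rec <- suppressWarnings(recommend_drugs(hist, panel, profile, seed = 3))
  expect_true(rec$low_confidence)
  expect_true(all(rec$predictions$predicted == 5.5))
})

test_that("tree-ensemble predictions stay within the panel target range", {
  for (learner in c("random_forest", "gradient_boosting")) {
    hist <- make_historical(seed = 6)
    panel <- drug_ids(hist)[1:6]
    profile <- stats::setNames(rnorm(6, 5, 2), panel)
    rec <- recommend_drugs(hist, panel, profile, learner = learner, seed = 2)
    expect_true(all(rec$predictions$predicted >= min(profile) - 1e-9))
    expect_true(all(rec$predictions$predicted <= max(profile) + 1e-9))
  }
})

test_that("results are deterministic given matrix, panel and seed", {
  hist <- make_historical(seed = 8)
  panel <- drug_ids(hist)[c(2, 4, 6, 8)]
  profile <- stats::setNames(rnorm(4, 5), panel)
  a <- suppressWarnings(recommend_drugs(hist, panel, profile, seed = 11))
  b <- suppressWarnings(recommend_drugs(hist, panel, profile, seed = 11))
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$ranking, b$ranking)
})

test_that("boosted stumps on a one-split dataset match the closed form", {
  # two historical cells; panel targets take one of two values, perfectly
  # separated by cell h1's activity: every stump splits the same way, so
  # after k rounds at shrinkage e the prediction approaches the leaf mean
  # geometrically: pred = leaf + (grand_mean - leaf) * (1 - e)^k
  # probe points sit clearly on either side of the h1 in {0,1} split
  vals <- matrix(c(0, 0, 1, 1, 1.5, 0.2,
                   5, 1, 2, 6, 3, 4),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("h1", "h2"), paste0("d", 1:6)))
  hist <- response_matrix(vals, "gdsc_pIC50", transformed = TRUE)
  panel <- c("d1", "d2", "d3", "d4")
  y <- c(d1 = 2, d2 = 2, d3 = 8, d4 = 8)  # split on h1 < 0.5
  rec <- recommend_drugs(hist, panel, y, learner = "gradient_boosting",
                         n_trees = 50, seed = 1)
  pred <- stats::setNames(rec$predictions$predicted, rec$predictions$drug_id)
  shrink <- (1 - 0.1)^50
  expect_equal(unname(pred["d5"]), 8 + (5 - 8) * shrink, tolerance = 1e-6)
  expect_equal(unname(pred["d6"]), 2 + (5 - 2) * shrink, tolerance = 1e-6)
})

test_that("rankings, hit flags and importances are coherent", {
  hist <- make_historical(n_cells = 20, n_drugs = 15, seed = 9)
  panel <- drug_ids(hist)[1:5]
  profile <- stats::setNames(rnorm(5, 6, 1.5), panel)
  rec <- suppressWarnings(recommend_drugs(hist, panel, profile, seed = 4))
  expect_setequal(rec$ranking, setdiff(drug_ids(hist), panel))
  expect_identical(rec$predictions$drug_id, rec$ranking)
  # descending-better scheme: predicted activity non-increasing down the list
  expect_true(all(diff(rec$predictions$predicted) <= 0))
  expect_setequal(rec$predicted_hits,
                  rec$predictions$drug_id[rec$predictions$predicted > 6])
  expect_equal(sum(rec$importances$importance), 1, tolerance = 1e-9)
  expect_true(all(rec$importances$importance >= 0))
  g <- glance(rec)
  expect_equal(g$n_predicted, 10)
  td <- tidy(rec)
  expect_identical(td$drug_id, rec$ranking)
})

test_that("tissue composition tabulates the most influential cell lines", {
  imp <- tibble::tibble(cell_id = sprintf("c%02d", 1:10),
                        importance = seq(0.19, 0.01, length.out = 10))
  ann <- tibble::tibble(cell_id = sprintf("c%02d", 1:9),
                        tissue = c(rep("lung", 4), rep("breast", 5)))
  comp <- tissue_composition(list(cell_id = imp$cell_id,
                                  importance = imp$importance) |>
                               tibble::as_tibble(),
                             ann, top_k = 10)
  expect_equal(sum(comp$n), 10)
  expect_equal(comp$n[comp$tissue == "unknown"], 1)  # c10 unannotated
  # all same tissue: count equals top_k
  ann2 <- tibble::tibble(cell_id = imp$cell_id, tissue = "skin")
  comp2 <- tissue_composition(imp, ann2, top_k = 6)
  expect_equal(comp2$n, 6)
  # top_k = all cells reproduces the overall tissue frequency
  comp3 <- tissue_composition(imp, ann2, top_k = 10)
  expect_equal(comp3$n, 10)
})
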