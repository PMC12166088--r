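test_that("activity transforms hit the documented anchor points and invert", {
  gdsc <- activity_scheme("gdsc_pIC50")
  expect_equal(scheme_transform(1e-6, gdsc), 6)   # 1 uM is the hit boundary
  expect_equal(scheme_transform(1, gdsc), 0)
  prism <- activity_scheme("prism_neglog2fc")
  expect_equal(scheme_transform(0.25, prism), 2)
  expect_true(2 > prism$hit_threshold)
  via <- activity_scheme("viability_percent")
  expect_equal(scheme_transform(42.5, via), 42.5)
  for (nm in c("gdsc_pIC50", "prism_neglog2fc", "viability_percent")) {
    x <- c(0.2, 1.5, 7)
    expect_equal(scheme_inverse(scheme_transform(x, nm), nm), x,
                 tolerance = 1e-12)
  }
})

test_that("hit rules respect their boundaries", {
  via <- activity_scheme("viability_percent")
  expect_true(is_hit(30.0, via))
  expect_false(is_hit(30.01, via))
  gdsc <- activity_scheme("gdsc_pIC50")
  expect_false(is_hit(6.0, gdsc))
  expect_true(is_hit(6.0001, gdsc))
  expect_true(is.na(is_hit(NA_real_, gdsc)))
})

test_that("reading a matrix handles missingness, orientation and bad input", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "m.csv")
  writeLines(c("cell_id,d1,d2", "c1,1.5,2.0", "c2,,3.0", "c3,0.5,na"), p1)
  m <- read_response_matrix(p1, "gdsc_pIC50", quiet = TRUE)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m$values)), 2L)
  expect_false(m$transformed)

  # transposed file with drugs as rows loads to the identical matrix
  p2 <- file.path(dir, "t.csv")
  writeLines(c("drug_id,c1,c2,c3", "d1,1.5,,0.5", "d2,2.0,3.0,na"), p2)
  m2 <- read_response_matrix(p2, "gdsc_pIC50", orientation = "drugs_by_rows",
                             quiet = TRUE)
  expect_identical(m2$values, m$values)

  # tab-delimited round trip through the writer
  p3 <- file.path(dir, "m.tsv")
  write_response_matrix(m, p3)
  expect_identical(read_response_matrix(p3, "gdsc_pIC50", quiet = TRUE)$values,
                   m$values)

  pdup <- file.path(dir, "dup.csv")
  writeLines(c("cell_id,d1,d2", "c1,1,2", "c1,3,4"), pdup)
  expect_error(read_response_matrix(pdup, "gdsc_pIC50", quiet = TRUE),
               "Duplicate")
  pbad <- file.path(dir, "bad.csv")
  writeLines(c("cell_id,d1,d2", "c1,1,2", "c2,oops,4"), pbad)
  expect_error(read_response_matrix(pbad, "gdsc_pIC50", quiet = TRUE),
               "c2.*d1|d1.*c2")
})

test_that("pruning removes sparse cells first, then sparse drugs", {
  vals <- matrix(1, 5, 5,
                 dimnames = list(paste0("c", 1:5), paste0("d", 1:5)))
  vals["c5", c("d1", "d2")] <- NA  # 2/5 missing -> cell removed at 0.2
  vals["c1", "d3"] <- NA           # 1/5 = 20%, at the limit -> cell kept;
                                   # d3 then missing in 1/4 = 25% of survivors
  m <- response_matrix(vals, "gdsc_pIC50")
  pr <- prune_matrix(m, 0.2, 0.2)
  expect_setequal(cell_ids(pr), c("c1", "c2", "c3", "c4"))
  expect_setequal(drug_ids(pr), c("d1", "d2", "d4", "d5"))

  # cell-first, drug-second ordering is observable: d3 is missing only in
  # cells that the cell filter removes, so it must survive
  vals2 <- matrix(1, 5, 4,
                  dimnames = list(paste0("c", 1:5), paste0("d", 1:4)))
  vals2["c5", c("d1", "d2", "d3")] <- NA  # 75% missing -> removed
  vals2["c4", "d3"] <- NA                 # 25% missing -> removed
  pr2 <- prune_matrix(response_matrix(vals2, "gdsc_pIC50"), 0.2, 0.2)
  expect_setequal(cell_ids(pr2), c("c1", "c2", "c3"))
  expect_setequal(drug_ids(pr2), c("d1", "d2", "d3", "d4"))

  # no missing values: identity at any limits
  full <- response_matrix(matrix(1:6, 2, 3,
                                 dimnames = list(c("a", "b"), c("x", "y", "z"))),
                          "gdsc_pIC50")
  expect_identical(prune_matrix(full, 0, 0)$values, full$values)

  # idempotence
  expect_identical(prune_matrix(pr, 0.2, 0.2)$values, pr$values)

  # absolute mode: c5 exceeds 1 missing entry, d3's single gap is tolerated
  expect_equal(dim(prune_matrix(m, 1, 1, mode = "absolute")), c(4L, 5L))
  allna <- response_matrix(
    matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    "gdsc_pIC50")
  expect_error(prune_matrix(allna, 0.2, 0.2), "every cell line")
})

test_that("transform_targets rejects non-positive raw values with location", {
  vals <- matrix(c(1e-6, -2, 1e-7, 3e-6), 2, 2,
                 dimnames = list(c("c1", "c2"), c("d1", "d2")))
  m <- response_matrix(vals, "gdsc_pIC50")
  expect_error(transform_targets(m), "c2.*d1")
  vals[2, 1] <- 1e-5
  tm <- transform_targets(response_matrix(vals, "gdsc_pIC50"))
  expect_equal(tm$values["c1", "d1"], 6)
  expect_true(tm$transformed)
  expect_error(transform_targets(tm), "already")
})

test_that("hit counts are permutation invariant and missing-aware", {
  m <- random_activity_matrix(12, 9, missing = 0.2, seed = 7)
  h <- call_hits(m)
  perm <- m[sample(cell_ids(m)), sample(drug_ids(m))]
  expect_equal(sum(call_hits(perm), na.rm = TRUE), sum(h, na.rm = TRUE))
  # an all-missing column is non-evaluable
  vals <- m$values
  vals[, "d03"] <- NA
  prev <- hit_prevalence(call_hits(response_matrix(vals, m$scheme,
                                                   transformed = TRUE)))
  expect_true(is.na(prev$prevalence[prev$drug_id == "d03"]))
  expect_equal(prev$n_obs[prev$drug_id == "d03"], 0L)
})

test_that("selective drugs use a strict prevalence bound over observed entries", {
  hits <- matrix(FALSE, 20, 3,
                 dimnames = list(sprintf("c%02d", 1:20), c("dA", "dB", "dC")))
  hits[1:3, "dA"] <- TRUE   # 15% -> selective
  hits[1:4, "dB"] <- TRUE   # exactly 20% -> not selective (strict <)
  sel <- selective_drugs(hits)
  expect_true(sel[["dA"]])
  expect_false(sel[["dB"]])
  expect_true(sel[["dC"]])  # zero hits is selective

  # prevalence over non-missing entries matches a brute-force loop
  m <- random_activity_matrix(15, 8, missing = 0.25, seed = 11)
  h <- call_hits(m)
  sel2 <- selective_drugs(h, 0.3)
  for (d in drug_ids(m)) {
    n_obs <- 0; n_hit <- 0
    for (cl in cell_ids(m)) {
      if (!is.na(h[cl, d])) {
        n_obs <- n_obs + 1
        n_hit <- n_hit + h[cl, d]
      }
    }
    expect_identical(unname(sel2[d]), n_obs > 0 && n_hit / n_obs < 0.3)
  }
})

test_that("long-format and glance views agree with the matrix", {
  m <- toy_viability()
  tl <- tidy(m)
  expect_equal(nrow(tl), 12)
  expect_equal(sum(tl$missing), 0)
  g <- glance(m)
  expect_equal(g$n_cells, 3)
  expect_equal(g$scheme, "viability_percent")
})
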