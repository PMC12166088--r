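# shared fixtures and independent oracles for the test suite

toy_viability <- function() {
  vals <- matrix(
    c(95, 20, 28, 88,
      30, 31, 60, 15,
      99, 97, 96, 95),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("c1", "c2", "c3"), c("d1", "d2", "d3", "d4"))
  )
  response_matrix(vals, "viability_percent", transformed = TRUE)
}

# small random activity matrix with optional missing entries
random_activity_matrix <- function(n_cells, n_drugs, missing = 0, seed = 1,
                                   scheme = "gdsc_pIC50") {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_cells * n_drugs, mean = 5, sd = 1.5),
                   n_cells, n_drugs,
                   dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                                   sprintf("d%02d", seq_len(n_drugs))))
    if (missing > 0) vals[runif(length(vals)) < missing] <- NA_real_
    response_matrix(vals, scheme, transformed = TRUE)
  })
}

# Independent plain-loop implementation of the correlation-diversity
# selection, written directly from its verbal description: drop the
# lowest-variance entities, rank survivors by median pairwise correlation,
# then walk the ranking taking references and knocking out everything
# correlated at or above the threshold with the current reference.
oracle_select_diverse <- function(X, threshold, keep_fraction = 0.5) {
  ids <- colnames(X)
  vars <- numeric(length(ids))
  for (j in seq_along(ids)) vars[j] <- var(X[, j], na.rm = TRUE)
  n_keep <- max(1, ceiling(keep_fraction * length(ids)))
  survivors <- ids[order(-vars, ids)][1:n_keep]
  k <- length(survivors)
  C <- diag(1, k)
  dimnames(C) <- list(survivors, survivors)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      xa <- X[, survivors[a]]
      xb <- X[, survivors[b]]
      ok <- !is.na(xa) & !is.na(xb)
      r <- if (sum(ok) < 3) 0 else suppressWarnings(cor(xa[ok], xb[ok]))
      C[a, b] <- if (is.na(r)) 0 else r
    }
  }
  med <- numeric(k)
  for (a in seq_len(k)) med[a] <- if (k == 1) 0 else median(C[a, -a])
  ranking <- survivors[order(med, survivors)]
  alive <- ranking
  refs <- character()
  while (length(alive) > 0) {
    ref <- alive[1]
    refs <- c(refs, ref)
    drop <- alive[C[ref, alive] >= threshold]
    alive <- setdiff(alive, union(drop, ref))
  }
  refs
}

# matrix holding the oracle's entity layout (entities as columns)
entity_values <- function(m, axis) {
  if (axis == "drugs") m$values else t(m$values)
}
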