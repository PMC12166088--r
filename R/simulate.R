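#' Simulate a drug screen with known low-rank ground truth
#'
#' Generates a cell-line by drug activity matrix with the statistical
#' structure the recommender exploits: a low-rank cross-cell-line response
#' surface with tissue clusters, calibrated hit prevalence, additive
#' Gaussian noise and missing-at-random entries.
#'
#' Cell factors are drawn around tissue-cluster means so that cells within
#' a cluster share `cluster_strength` of their factor variance; drug
#' factors are independent standard normals. The rank-`latent_rank` surface
#' is scaled to `activity_sd` and shifted so that the realised hit
#' prevalence (under the scheme's hit rule) matches
#' `target_hit_prevalence`; the shift and scale are folded into the stored
#' factors, so the noiseless truth equals
#' `cell_factors %*% t(drug_factors)`. Viability values are clamped at 0
#' (which cannot change a hit call, since the clamp floor is below the 30%
#' threshold; clamped entries deviate from the factor product).
#'
#' Defaults are a GDSC1-like screen: 800 cells x 300 drugs on the pIC50
#' scale with 17.8% hit prevalence and 10% missingness.
#'
#' @param n_cells,n_drugs Matrix dimensions.
#' @param latent_rank Rank of the shared response structure; default 3.
#' @param n_tissue_clusters Number of tissue-of-origin clusters; default 5.
#' @param cluster_strength Fraction of cell-factor variance shared within a
#'   tissue cluster, in `[0, 1]`; default 0.5.
#' @param noise_sd Standard deviation of the measurement noise on the
#'   activity scale; default 0.3.
#' @param missing_fraction Missing-at-random entry fraction; default 0.1.
#' @param scheme An [activity_scheme()] or name; default `"gdsc_pIC50"`.
#' @param target_hit_prevalence Desired fraction of hits; default 0.178.
#' @param activity_sd Scale of the activity surface; default 1.5 for the
#'   log-activity schemes and 25 for viability.
#' @param seed Integer seed; the same seed reproduces the screen exactly.
#' @return A list of class `synthetic_screen`:
#'   * `matrix` — the observed [response_matrix()] (activity scale);
#'   * `truth` — `cell_factors`, `drug_factors`, `noiseless`
#'     (the factor product, clamped for viability), `hits`
#'     (hit calls on the noiseless surface), `tissue` labels;
#'   * `annotations` — tibble (`cell_id`, `tissue`).
#' @export
simulate_screen <- function(n_cells = 800, n_drugs = 300, latent_rank = 3,
                            n_tissue_clusters = 5, cluster_strength = 0.5,
                            noise_sd = 0.3, missing_fraction = 0.1,
                            scheme = "gdsc_pIC50",
                            target_hit_prevalence = 0.178,
                            activity_sd = NULL, seed = 1) {
  scheme <- as_activity_scheme(scheme)
  stopifnot(latent_rank >= 1, noise_sd >= 0,
            cluster_strength >= 0, cluster_strength <= 1,
            missing_fraction >= 0, missing_fraction < 1,
            target_hit_prevalence > 0, target_hit_prevalence < 1)
  if (is.null(activity_sd)) {
    activity_sd <- if (scheme$name == "viability_percent") 25 else 1.5
  }
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  withr::with_seed(as.integer(seed), {
    tissue_idx <- sample(n_tissue_clusters, n_cells, replace = TRUE)
    mu <- matrix(rnorm(n_tissue_clusters * latent_rank),
                 n_tissue_clusters, latent_rank)
    U <- sqrt(cluster_strength) * mu[tissue_idx, , drop = FALSE] +
      sqrt(1 - cluster_strength) *
        matrix(rnorm(n_cells * latent_rank), n_cells, latent_rank)
    V <- matrix(rnorm(n_drugs * latent_rank), n_drugs, latent_rank)
    Z <- U %*% t(V)
    s <- activity_sd / sd(Z)
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_cells * n_drugs, sd = noise_sd), n_cells, n_drugs)
    } else 0
    M0 <- s * Z + noise
    p <- target_hit_prevalence
    shift <- if (scheme$hit_direction == "greater") {
      scheme$hit_threshold - quantile(M0, 1 - p, names = FALSE)
    } else {
      scheme$hit_threshold - quantile(M0, p, names = FALSE)
    }
    observed <- M0 + shift
    noiseless <- s * Z + shift
    if (scheme$name == "viability_percent") {
      observed[observed < 0] <- 0
      noiseless[noiseless < 0] <- 0
    }
    realized <- mean(is_hit(observed, scheme))
    tol <- 3 * sqrt(p * (1 - p) / (n_cells * n_drugs)) + 1 / (n_cells * n_drugs)
    if (abs(realized - p) > tol) {
      abort(paste0("Target hit prevalence ", p, " unattainable under scheme '",
                   scheme$name, "' (realised ", signif(realized, 3), ")."))
    }
    mask <- matrix(runif(n_cells * n_drugs) < missing_fraction,
                   n_cells, n_drugs)
    observed[mask] <- NA_real_
    dimnames(observed) <- list(cells, drugs)
    dimnames(noiseless) <- list(cells, drugs)
    hits_true <- is_hit(noiseless, scheme)
    cell_factors <- cbind(U, 1)
    drug_factors <- cbind(s * V, shift)
    rownames(cell_factors) <- cells
    rownames(drug_factors) <- drugs
    tissue <- sprintf("tissue_%02d", tissue_idx)
    structure(
      list(
        matrix = response_matrix(observed, scheme, transformed = TRUE),
        truth = list(cell_factors = cell_factors,
                     drug_factors = drug_factors,
                     noiseless = noiseless, hits = hits_true,
                     tissue = stats::setNames(tissue, cells)),
        annotations = tibble(cell_id = cells, tissue = tissue)
      ),
      class = "synthetic_screen"
    )
  })
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("<synthetic_screen>\n")
  print(x$matrix)
  cat("  tissues: ", length(unique(x$annotations$tissue)),
      "; latent rank: ", ncol(x$truth$cell_factors) - 1, "\n", sep = "")
  invisible(x)
}

#' Synthetic stand-in for a small post-biopsy viability screen
#'
#' A 24 cell-line x 35 drug viability-percent screen with on average about
#' 4.4 hits per cell line (viability <= 30%) and at most 5 missing entries
#' per cell line and per drug, mirroring the scale of an ex vivo
#' FDA-approved-drug panel screened on fresh patient biopsies. Useful as a
#' drop-in input for leave-one-out protocol tests; it survives absolute
#' 5/5 pruning unchanged by construction.
#'
#' @param seed Integer seed.
#' @return A `synthetic_screen`; see [simulate_screen()].
#' @export
make_biopsy_screen <- function(seed = 1) {
  scr <- simulate_screen(
    n_cells = 24, n_drugs = 35, latent_rank = 2, n_tissue_clusters = 3,
    cluster_strength = 0.5, noise_sd = 5, missing_fraction = 0,
    scheme = "viability_percent", target_hit_prevalence = 4.36 / 35,
    activity_sd = 25, seed = seed
  )
  # sparse MAR mask constrained to <= 5 missing per cell line and per drug
  vals <- scr$matrix$values
  withr::with_seed(derive_seed(seed, "biopsy_mask"), {
    for (attempt in 1:100) {
      mask <- matrix(runif(length(vals)) < 0.04, nrow(vals), ncol(vals))
      if (all(rowSums(mask) <= 5) && all(colSums(mask) <= 5)) break
    }
  })
  if (any(rowSums(mask) > 5) || any(colSums(mask) > 5)) {
    mask[] <- FALSE # give up on masking rather than break the 5/5 bound
  }
  vals[mask] <- NA_real_
  scr$matrix <- response_matrix(vals, scr$matrix$scheme, transformed = TRUE)
  scr
}
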