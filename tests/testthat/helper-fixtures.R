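# Shared fixtures and independent oracles used across test files.

# Build a landscape grid directly from a cover matrix.
grid_from_cover <- function(cover, n_rows, n_cols,
                            modifiable = rep(TRUE, nrow(cover))) {
  landscape_grid(cover, n_rows, n_cols, modifiable,
                 classes = lc_class_names(ncol(cover)))
}

# Random valid cover matrix (rows sum to 1).
random_cover <- function(n, k = 24, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

# A flat climate field over a grid (every cell identical).
flat_climate <- function(grid, bio1 = 10, bio3 = 35, bio12 = 800,
                         bio13 = 200, scenario = "baseline") {
  climate_field(grid$cell_id, scenario,
                rep(bio1, nrow(grid)), rep(bio3, nrow(grid)),
                rep(bio12, nrow(grid)), rep(bio13, nrow(grid)))
}

# Hand-rolled land-use model object for scenario/impact tests.
make_model <- function(beta, cov = NULL, id = "spX", prior_sd = 1) {
  p <- length(beta)
  structure(
    list(species_id = id, beta_mean = beta,
         beta_cov = if (is.null(cov)) matrix(0, p, p) else cov,
         prior = prior_spec(prior_sd, p), converged = TRUE,
         eval_auc = NA_real_, threshold = NA_real_),
    class = "landuse_model")
}

# ---- independent oracles --------------------------------------------------

# AUC by brute-force enumeration of all presence x absence pairs.
auc_pairwise_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Threshold by independent exhaustive scan over midpoint candidates.
threshold_exhaustive_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  if (length(s) == 1) return(s)
  best_j <- -Inf; best_c <- NA
  for (i in seq_len(length(s) - 1)) {
    ct <- (s[i] + s[i + 1]) / 2
    sens <- mean(scores[labels] >= ct)
    spec <- mean(scores[!labels] < ct)
    if (sens + spec > best_j + 1e-12) { best_j <- sens + spec; best_c <- ct }
  }
  best_c
}

# Exact Poisson-binomial pmf by direct convolution.
pb_pmf_oracle <- function(p) {
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  f
}

# Exact central interval of a Poisson-binomial count (inverse CDF).
pb_interval_oracle <- function(p, level = 0.95) {
  F <- cumsum(pb_pmf_oracle(p))
  a <- (1 - level) / 2
  c(min(which(F >= a)) - 1, min(which(F >= 1 - a)) - 1)
}
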