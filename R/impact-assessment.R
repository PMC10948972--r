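#' Expected habitable area of a species (in cells)
#'
#' The sum of occurrence probability over the modifiable cells, interpreted
#' as an expected number of occupied cells.
#'
#' @param surface per-cell probability vector (a `probability_surface`).
#' @param grid a [landscape_grid()].
#' @return expected cell count.
#' @export
expected_area <- function(surface, grid) {
  stopifnot(length(surface) == nrow(grid))
  sum(surface[grid$modifiable])
}

#' Linearised (delta-method) variance of expected habitable area
#'
#' Propagates the Gaussian posterior of the land-use coefficients through the
#' expected-area sum by first-order linearisation: with gradient
#' `g = sum over masked modifiable cells of p(1-p) x_cell` (covariates in
#' percentage points), the variance is `g' Cov g`.
#'
#' @param model a `landuse_model` with positive-semidefinite `beta_cov`.
#' @param grid a [landscape_grid()].
#' @param mask logical climate-mask vector over grid cells.
#' @return variance of the expected area.
#' @export
area_variance_linearised <- function(model, grid, mask) {
  ev <- eigen(model$beta_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("beta_cov must be positive semidefinite")
  }
  sel <- grid$modifiable & mask
  if (!any(sel)) return(0)
  X <- cover_percent(grid)[sel, , drop = FALSE]
  p <- plogis(drop(X %*% model$beta_mean))
  g <- drop(crossprod(X, p * (1 - p)))
  drop(t(g) %*% model$beta_cov %*% g)
}

# Draw coefficient vectors from the Gaussian posterior (rows = draws).
# Eigen-based square root so rank-deficient (including exactly zero)
# covariances are handled without jitter.
posterior_draws <- function(model, n_draws, seed) {
  set.seed(seed)
  p <- length(model$beta_mean)
  e <- eigen(model$beta_cov, symmetric = TRUE)
  R <- diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  Z <- matrix(rnorm(n_draws * p), n_draws, p)
  sweep(Z %*% R, 2, model$beta_mean, `+`)
}

# Expected areas over modifiable+masked cells for a matrix of coefficient
# draws, computed in chunks to bound memory.
draw_areas <- function(draws, grid, mask, chunk = 500) {
  sel <- grid$modifiable & mask
  n_draws <- nrow(draws)
  if (!any(sel)) return(numeric(n_draws))
  X <- cover_percent(grid)[sel, , drop = FALSE]
  out <- numeric(n_draws)
  for (i in seq(1, n_draws, by = chunk)) {
    j <- min(i + chunk - 1, n_draws)
    out[i:j] <- colSums(plogis(X %*% t(draws[i:j, , drop = FALSE])))
  }
  out
}

#' Posterior probability of a relative change in habitable area
#'
#' Draws coefficient vectors from the Gaussian posterior and, per draw,
#' computes baseline and scenario expected areas with shared coefficients.
#' `p_gain` is the fraction of draws with scenario area at least
#' `(1 + change_level)` times the baseline area; `p_loss` uses
#' `(1 - change_level)`. A draw with zero baseline area counts as a gain iff
#' its scenario area is positive, and never as a loss.
#'
#' @param model a `landuse_model`.
#' @param grid_base,grid_scen baseline and scenario landscapes.
#' @param mask_base,mask_scen climate masks paired with each landscape.
#' @param change_level relative threshold (default 0.10).
#' @param n_draws posterior draws (default 10000).
#' @param seed seed for the draws.
#' @return list `p_gain`, `p_loss`, `n_zero_base` (count of zero-baseline
#'   draws).
#' @export
prob_relative_change <- function(model, grid_base, mask_base,
                                 grid_scen, mask_scen,
                                 change_level = 0.10, n_draws = 10000,
                                 seed = 1L) {
  draws <- posterior_draws(model, n_draws, seed)
  a_base <- draw_areas(draws, grid_base, mask_base)
  a_scen <- draw_areas(draws, grid_scen, mask_scen)
  cls <- classify_change(a_base, a_scen, change_level)
  list(p_gain = mean(cls$gain), p_loss = mean(cls$loss),
       n_zero_base = sum(a_base == 0))
}

# Gain/loss indicators per draw, with the zero-baseline convention.
classify_change <- function(a_base, a_scen, change_level) {
  zero <- a_base == 0
  gain <- ifelse(zero, a_scen > 0, a_scen >= (1 + change_level) * a_base)
  loss <- !zero & a_scen <= (1 - change_level) * a_base
  list(gain = gain, loss = loss)
}

#' Distribution of the number of species gaining or losing
#'
#' Given aligned per-draw indicator matrices (draws x species; species'
#' posteriors independent), counts the species gaining/losing per draw and
#' summarises the count distribution by its mean and central 95% interval
#' (inverse-CDF quantiles, appropriate for an integer-valued distribution).
#'
#' @param indicators logical or 0/1 matrix, draws in rows, species in
#'   columns.
#' @param level credibility level (default 0.95).
#' @return list `mean`, `lower`, `upper`, `counts` (per-draw counts).
#' @export
species_count_distribution <- function(indicators, level = 0.95) {
  counts <- rowSums(indicators)
  a <- (1 - level) / 2
  q <- quantile(counts, c(a, 1 - a), type = 1, names = FALSE)
  list(mean = mean(counts), lower = q[1], upper = q[2], counts = counts)
}

#' Assess scenario impacts across species with posterior uncertainty
#'
#' The headline impact computation: for every retained species, draws from
#' its coefficient posterior are pushed through baseline (current land use +
#' reference-climate mask) and scenario (allocated land use + scenario-climate
#' mask) expected-area sums. Point estimates use the posterior-mean
#' coefficients; uncertainty comes from the aligned draws (species
#' independent).
#'
#' @param models list of `landuse_model`s.
#' @param grid_base baseline [landscape_grid()].
#' @param grid_scen scenario landscape (may equal `grid_base` for no-change).
#' @param masks_base,masks_scen named lists (by species id) of logical climate
#'   masks paired with the baseline and scenario.
#' @param change_level relative gain/loss threshold (default 0.10).
#' @param n_draws posterior draws per species (default 10000).
#' @param seed integer seed (a per-species substream is derived from it).
#' @return object of class `impact_summary`: list with `species` (data frame
#'   `species_id`, `area_baseline`, `area_scenario`, `sd_area`, `p_gain10`,
#'   `p_loss10`), `summary` (data frame with average habitable fraction of
#'   modifiable cells and 95% credibility interval, gain/loss counts with
#'   intervals), `n_modifiable` and `change_level`.
#' @export
assess_impacts <- function(models, grid_base, grid_scen,
                           masks_base, masks_scen,
                           change_level = 0.10, n_draws = 10000, seed = 1L) {
  stopifnot(length(models) >= 1)
  n_mod <- sum(grid_base$modifiable)
  S <- length(models)
  gain_mat <- matrix(FALSE, n_draws, S)
  loss_mat <- matrix(FALSE, n_draws, S)
  mean_frac_draws <- numeric(n_draws)
  sp_rows <- vector("list", S)
  for (s in seq_len(S)) {
    m <- models[[s]]
    mb <- masks_base[[m$species_id]]
    ms <- masks_scen[[m$species_id]]
    draws <- posterior_draws(m, n_draws, stream_seed(seed, m$species_id))
    a_base <- draw_areas(draws, grid_base, mb)
    a_scen <- draw_areas(draws, grid_scen, ms)
    cls <- classify_change(a_base, a_scen, change_level)
    gain_mat[, s] <- cls$gain
    loss_mat[, s] <- cls$loss
    mean_frac_draws <- mean_frac_draws + a_scen / n_mod / S
    area_b <- expected_area(predict_masked_probability(m, grid_base, mb), grid_base)
    area_s <- expected_area(predict_masked_probability(m, grid_scen, ms), grid_scen)
    sp_rows[[s]] <- data.frame(
      species_id = m$species_id,
      area_baseline = area_b,
      area_scenario = area_s,
      sd_area = sqrt(area_variance_linearised(m, grid_scen, ms)),
      p_gain10 = mean(cls$gain),
      p_loss10 = mean(cls$loss)
    )
  }
  species <- do.call(rbind, sp_rows)
  gains <- species_count_distribution(gain_mat)
  losses <- species_count_distribution(loss_mat)
  frac_ci <- quantile(mean_frac_draws, c(0.025, 0.975), names = FALSE)
  summary <- data.frame(
    avg_habitable_fraction = mean(species$area_scenario) / n_mod,
    avg_habitable_lower = frac_ci[1],
    avg_habitable_upper = frac_ci[2],
    n_gain10 = gains$mean, n_gain10_lower = gains$lower,
    n_gain10_upper = gains$upper,
    n_loss10 = losses$mean, n_loss10_lower = losses$lower,
    n_loss10_upper = losses$upper
  )
  structure(list(species = species, summary = summary,
                 n_modifiable = n_mod, change_level = change_level),
            class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("impact_summary: %d species, %d modifiable cells\n",
           "  average habitable fraction: %.3f (%.3f-%.3f)\n",
           "  species gaining >%d%%: %.1f (%d-%d); losing: %.1f (%d-%d)\n"),
    nrow(x$species), x$n_modifiable,
    s$avg_habitable_fraction, s$avg_habitable_lower, s$avg_habitable_upper,
    round(100 * x$change_level),
    s$n_gain10, s$n_gain10_lower, s$n_gain10_upper,
    s$n_loss10, s$n_loss10_lower, s$n_loss10_upper
  ))
  invisible(x)
}
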