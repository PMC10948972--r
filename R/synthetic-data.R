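#' Configuration for the synthetic study system
#'
#' Bundles every knob of the virtual-species simulator: grid size, the
#' Dirichlet concentration controlling land-cover composition, spatial
#' smoothing of cover, the fraction of cells open to land-use change, linear
#' climate gradients with seeded noise, the future-scenario climate deltas,
#' the spread of true land-use coefficients, and the detection (thinning)
#' probability of the presence-only recording process.
#'
#' Defaults describe the study conditions used throughout the package: a
#' 50 x 50 grid of 2x2 km cells, 24 land-cover classes with a flat Dirichlet
#' concentration smoothed once to produce clustered cover, 42% of cells
#' modifiable, temperate-maritime climate gradients, a +2 degree / +10%
#' precipitation future, true coefficients of sd 0.2 log-odds per percentage
#' point, and a 0.5 detection probability per occupied cell.
#'
#' @param n_rows,n_cols grid dimensions in cells.
#' @param n_classes number of land-cover classes (default 24).
#' @param n_species number of virtual species.
#' @param dirichlet_concentration positive numeric vector of length
#'   `n_classes`; per-cell cover proportions are Dirichlet with this
#'   concentration before smoothing.
#' @param spatial_smoothing_passes non-negative integer; passes of 4-neighbour
#'   averaging applied to cover to induce spatial autocorrelation.
#' @param modifiable_fraction probability that a cell is modifiable.
#' @param climate_gradients list with elements `bio1`, `bio12`, `bio3`, each a
#'   list `(intercept, slope, noise_sd)` (slope is per grid row), and
#'   `wet_fraction`, the fraction of annual precipitation falling in the
#'   wettest month (must lie in (1/12, 1]).
#' @param future_delta_bio1 additive future change in mean annual temperature
#'   (degrees C).
#' @param future_precip_ratio multiplicative future change in precipitation.
#' @param coeff_sd_true sd of true land-use coefficients (log-odds per
#'   percentage point of cover).
#' @param thinning_prob detection probability: chance an occupied cell yields
#'   an occurrence record.
#' @param seed integer run seed; all generation is a pure function of it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 50, n_cols = 50,
                             n_classes = 24, n_species = 30,
                             dirichlet_concentration = rep(1, n_classes),
                             spatial_smoothing_passes = 1,
                             modifiable_fraction = 0.42,
                             climate_gradients = list(
                               bio1 = list(intercept = 8, slope = 0.08, noise_sd = 0.3),
                               bio12 = list(intercept = 600, slope = 8, noise_sd = 25),
                               bio3 = list(intercept = 35, slope = 0, noise_sd = 2),
                               wet_fraction = 0.25
                             ),
                             future_delta_bio1 = 2,
                             future_precip_ratio = 1.1,
                             coeff_sd_true = 0.2,
                             thinning_prob = 0.5,
                             seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_classes >= 1, n_species >= 1,
            spatial_smoothing_passes >= 0)
  if (length(dirichlet_concentration) != n_classes ||
      any(!is.finite(dirichlet_concentration)) ||
      any(dirichlet_concentration <= 0)) {
    stop("dirichlet_concentration must be a strictly positive vector of length n_classes")
  }
  check_prob(modifiable_fraction)
  check_prob(thinning_prob)
  wf <- climate_gradients$wet_fraction %||% 0.25
  if (wf <= 1 / 12 || wf > 1) stop("wet_fraction must lie in (1/12, 1]")
  if (coeff_sd_true < 0) stop("coeff_sd_true must be non-negative")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_classes = as.integer(n_classes), n_species = as.integer(n_species),
         dirichlet_concentration = dirichlet_concentration,
         spatial_smoothing_passes = as.integer(spatial_smoothing_passes),
         modifiable_fraction = modifiable_fraction,
         climate_gradients = climate_gradients,
         future_delta_bio1 = future_delta_bio1,
         future_precip_ratio = future_precip_ratio,
         coeff_sd_true = coeff_sd_true,
         thinning_prob = thinning_prob,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# One pass of 4-neighbour averaging on a row-major cell vector.
smooth_field <- function(v, n_rows, n_cols) {
  M <- matrix(v, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  S <- M
  W <- matrix(1, n_rows, n_cols)
  if (n_rows > 1) {
    S[-1, ] <- S[-1, ] + M[-n_rows, ]; W[-1, ] <- W[-1, ] + 1
    S[-n_rows, ] <- S[-n_rows, ] + M[-1, ]; W[-n_rows, ] <- W[-n_rows, ] + 1
  }
  if (n_cols > 1) {
    S[, -1] <- S[, -1] + M[, -n_cols]; W[, -1] <- W[, -1] + 1
    S[, -n_cols] <- S[, -n_cols] + M[, -1]; W[, -n_cols] <- W[, -n_cols] + 1
  }
  as.vector(t(S / W))
}

#' Generate a synthetic landscape grid
#'
#' Draws per-cell land-cover proportions from a Dirichlet distribution with
#' the configured concentration, applies the configured number of 4-neighbour
#' smoothing passes (then renormalises), and assigns independent modifiable
#' flags with the configured probability. Pure function of `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [landscape_grid()].
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stream_seed(config$seed, "landscape"))
  n <- config$n_rows * config$n_cols
  k <- config$n_classes
  alpha <- config$dirichlet_concentration
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  rs <- rowSums(g)
  rs[rs == 0] <- 1  # pathological all-zero draw: leave the row at zero, fixed below
  g <- g / rs
  # a row can still be all-zero if every gamma draw underflowed; fall back to flat
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k
  if (config$spatial_smoothing_passes > 0) {
    for (p in seq_len(config$spatial_smoothing_passes)) {
      g <- apply(g, 2, smooth_field, n_rows = config$n_rows, n_cols = config$n_cols)
    }
    g <- g / rowSums(g)
  }
  modifiable <- runif(n) < config$modifiable_fraction
  landscape_grid(g, config$n_rows, config$n_cols, modifiable,
                 classes = lc_class_names(k))
}

#' Construct a climate field
#'
#' @param cell_id integer cell ids.
#' @param scenario scenario label (e.g. "baseline", "future").
#' @param bio1 mean annual temperature (degrees C).
#' @param bio3 isothermality (percent).
#' @param bio12 annual precipitation (mm).
#' @param bio13 precipitation of the wettest month (mm).
#' @return an object of class `climate_field` (also a data frame).
#' @export
climate_field <- function(cell_id, scenario, bio1, bio3, bio12, bio13) {
  df <- data.frame(cell_id = cell_id, scenario = scenario,
                   bio1 = bio1, bio3 = bio3, bio12 = bio12, bio13 = bio13)
  if (any(df$bio12 < df$bio13 - 1e-9) || any(df$bio13 < df$bio12 / 12 - 1e-9)) {
    stop("climate field must satisfy bio12 >= bio13 >= bio12/12")
  }
  structure(df, class = c("climate_field", "data.frame"))
}

#' Generate baseline and future climate fields for a grid
#'
#' Baseline variables follow the configured linear row gradients plus seeded
#' Gaussian noise; the wettest-month precipitation is a fixed fraction of the
#' annual total (guaranteeing `bio13 >= bio12/12`). The future field shifts
#' temperature additively by `future_delta_bio1` and scales both precipitation
#' variables by `future_precip_ratio`, leaving isothermality unchanged.
#'
#' @param grid a [landscape_grid()].
#' @param config a [synthetic_config()].
#' @return list with `climate_field` elements `baseline` and `future`.
#' @export
gen_climate <- function(grid, config) {
  stopifnot(inherits(config, "synthetic_config"), nrow(grid) > 0)
  set.seed(stream_seed(config$seed, "climate"))
  cg <- config$climate_gradients
  r <- grid$row
  n <- nrow(grid)
  lin <- function(spec) spec$intercept + spec$slope * r +
    if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  bio1 <- lin(cg$bio1)
  bio12 <- pmax(lin(cg$bio12), 1)
  bio3 <- pmin(pmax(lin(cg$bio3), 0), 100)
  bio13 <- bio12 * (cg$wet_fraction %||% 0.25)
  baseline <- climate_field(grid$cell_id, "baseline", bio1, bio3, bio12, bio13)
  future <- climate_field(grid$cell_id, "future",
                          bio1 + config$future_delta_bio1, bio3,
                          bio12 * config$future_precip_ratio,
                          bio13 * config$future_precip_ratio)
  list(baseline = baseline, future = future)
}

#' Generate virtual species with known ground truth
#'
#' Each species gets a rectilinear climatic envelope on BIO1 and BIO12 (bounds
#' sampled inside the observed baseline climate range: a half-width drawn
#' uniformly between 20% and 40% of the observed range, centred so the box
#' stays inside it) and a vector of true land-use coefficients drawn iid
#' `N(0, coeff_sd_true^2)` in log-odds per percentage point of cover.
#'
#' @param config a [synthetic_config()].
#' @param climate a baseline `climate_field` covering the grid.
#' @return list of `true_species` objects, each with `species_id`,
#'   `envelope_bounds` (list of `c(lower, upper)` for bio1 and bio12),
#'   `true_beta` and `thinning_prob`.
#' @export
gen_species <- function(config, climate) {
  stopifnot(inherits(config, "synthetic_config"), config$n_species >= 1)
  set.seed(stream_seed(config$seed, "species"))
  draw_bounds <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1e-6
    half <- runif(1, 0.2, 0.4) * (hi - lo)
    centre <- runif(1, lo + half, hi - half)
    c(lower = centre - half, upper = centre + half)
  }
  lapply(seq_len(config$n_species), function(i) {
    b1 <- draw_bounds(climate$bio1)
    b12 <- draw_bounds(climate$bio12)
    beta <- rnorm(config$n_classes, 0, config$coeff_sd_true)
    structure(
      list(species_id = sprintf("sp%03d", i),
           envelope_bounds = list(bio1 = b1, bio12 = b12),
           true_beta = beta,
           thinning_prob = config$thinning_prob),
      class = "true_species"
    )
  })
}

#' True climatic suitability of grid cells for a virtual species
#'
#' @param species a `true_species`.
#' @param climate a `climate_field` covering the grid.
#' @return logical vector: cell inside the species' true envelope.
#' @export
true_suitable <- function(species, climate) {
  b <- species$envelope_bounds
  climate$bio1 >= b$bio1[["lower"]] & climate$bio1 <= b$bio1[["upper"]] &
    climate$bio12 >= b$bio12[["lower"]] & climate$bio12 <= b$bio12[["upper"]]
}

#' True occurrence probability of a virtual species per cell
#'
#' Logistic in the true coefficients on cover percentages inside the species'
#' climatic envelope, exactly zero outside it.
#'
#' @param species a `true_species`.
#' @param grid a [landscape_grid()].
#' @param climate a `climate_field` covering the grid.
#' @return numeric vector of occurrence probabilities per cell.
#' @export
true_occurrence_prob <- function(species, grid, climate) {
  p <- plogis(as.vector(cover_percent(grid) %*% species$true_beta))
  p * true_suitable(species, climate)
}

#' Sample presence-only occurrence records from virtual species
#'
#' Per species and cell, a record is emitted with probability
#' `occurrence_prob * thinning_prob`, where the occurrence probability is the
#' logistic land-use response masked by the true climatic envelope. Each
#' record carries a 1-km sub-cell location (uniform among the four 1x1 km
#' quarters of the 2x2 km cell) and a day-resolved date drawn uniformly in
#' 1970-2020, mimicking opportunistically collected biological records.
#'
#' @param species list of `true_species`.
#' @param grid a [landscape_grid()].
#' @param climate a baseline `climate_field` covering every grid cell.
#' @param config a [synthetic_config()].
#' @return data frame of occurrence records with columns `species_id`,
#'   `x_1km`, `y_1km`, `date`, `spatial_precision_m`, `taxon_rank`.
#' @export
sample_occurrences <- function(species, grid, climate, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stream_seed(config$seed, "records"))
  date_pool <- seq(as.Date("1970-01-01"), as.Date("2020-12-31"), by = "day")
  out <- lapply(species, function(sp) {
    p <- true_occurrence_prob(sp, grid, climate) * sp$thinning_prob
    hit <- runif(nrow(grid)) < p
    idx <- which(hit)
    if (length(idx) == 0) return(NULL)
    data.frame(
      species_id = sp$species_id,
      x_1km = grid$col[idx] * 2L + sample(0:1, length(idx), replace = TRUE),
      y_1km = grid$row[idx] * 2L + sample(0:1, length(idx), replace = TRUE),
      date = date_pool[sample.int(length(date_pool), length(idx), replace = TRUE)],
      spatial_precision_m = 1000,
      taxon_rank = "species"
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(species_id = character(), x_1km = integer(),
                      y_1km = integer(), date = as.Date(character()),
                      spatial_precision_m = numeric(), taxon_rank = character())
  }
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study system
#'
#' Convenience wrapper running [gen_landscape()], [gen_climate()],
#' [gen_species()] and [sample_occurrences()] in sequence.
#'
#' @param config a [synthetic_config()].
#' @return list with `grid`, `climate` (list baseline/future), `species`,
#'   `occurrences` and the `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  grid <- gen_landscape(config)
  climate <- gen_climate(grid, config)
  species <- gen_species(config, climate$baseline)
  occurrences <- sample_occurrences(species, grid, climate$baseline, config)
  list(grid = grid, climate = climate, species = species,
       occurrences = occurrences, config = config)
}
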