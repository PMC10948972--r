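# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert production-change percentages to land-exchange fractions
#'
#' National-scale arithmetic turning a percent reduction in grazing
#' production and a percent increase in horticulture production into cell
#' counts and grazing-land shares. Counts are rounded half away from zero;
#' the natural-cover cell count is the difference of the rounded totals (not
#' independently rounded), and the shares are the horticulture / natural cell
#' counts as fractions of current grazing cells.
#'
#' @param grazing_cells_current current national grazing cell count.
#' @param grazing_reduction_pct percent reduction in grazing (e.g. 23).
#' @param hort_cells_current current national horticulture cell count.
#' @param hort_increase_pct percent increase in horticulture (e.g. 334).
#' @return object of class `scenario_arithmetic`: list with
#'   `grazing_cells_remaining`, `cells_to_redistribute`, `hort_cells_total`,
#'   `natural_cells`, `pct_to_hort`, `pct_to_natural` (the last two as
#'   fractions of current grazing).
#' @export
scenario_from_production <- function(grazing_cells_current,
                                     grazing_reduction_pct,
                                     hort_cells_current,
                                     hort_increase_pct) {
  stopifnot(grazing_cells_current >= 0, grazing_reduction_pct >= 0,
            hort_cells_current >= 0, hort_increase_pct >= 0)
  red <- grazing_reduction_pct / 100
  inc <- hort_increase_pct / 100
  remaining <- round_half_up(grazing_cells_current * (1 - red))
  redistribute <- round_half_up(grazing_cells_current * red)
  hort_total <- round_half_up(hort_cells_current * (1 + inc))
  natural <- redistribute - hort_total
  if (natural < 0) {
    stop("scenario infeasible: horticulture expansion exceeds redistributable grazing land")
  }
  structure(
    list(grazing_cells_current = grazing_cells_current,
         grazing_cells_remaining = remaining,
         cells_to_redistribute = redistribute,
         hort_cells_total = hort_total,
         natural_cells = natural,
         pct_to_hort = hort_total / grazing_cells_current,
         pct_to_natural = natural / grazing_cells_current),
    class = "scenario_arithmetic"
  )
}

#' Define a land-use change scenario
#'
#' @param name scenario label.
#' @param pct_to_hort fraction of national grazing area converted to
#'   horticulture (0-1).
#' @param pct_to_natural fraction converted to natural covers (0-1).
#' @param allocation `"local"`, `"best"` or `"worst"`.
#' @param climate climate scenario the species masks use: `"baseline"` or
#'   `"future"`.
#' @param ref_climate climate scenario of the no-change comparator used for
#'   relative-change statistics (default `"baseline"`).
#' @return object of class `scenario`.
#' @export
make_scenario <- function(name, pct_to_hort = 0, pct_to_natural = 0,
                          allocation = c("local", "best", "worst"),
                          climate = c("baseline", "future"),
                          ref_climate = "baseline") {
  allocation <- match.arg(allocation)
  climate <- match.arg(climate)
  stopifnot(pct_to_hort >= 0, pct_to_natural >= 0,
            pct_to_hort + pct_to_natural <= 1)
  structure(list(name = name, pct_to_hort = pct_to_hort,
                 pct_to_natural = pct_to_natural, allocation = allocation,
                 climate = climate, ref_climate = ref_climate),
            class = "scenario")
}

#' Local (uniform) allocation of grazing-land conversion
#'
#' In every modifiable cell, each grazing class is scaled by
#' `1 - pct_to_hort - pct_to_natural`; horticulture gains `pct_to_hort` times
#' the cell's grazing total and each of the three natural covers gains one
#' third of `pct_to_natural` times the cell's grazing total. Non-modifiable
#' cells (and cells without grazing) are unchanged; per-cell sums remain 1.
#' Because the proportions are identical in every cell, the national exchange
#' equals the same proportions of national grazing.
#'
#' @param grid a [landscape_grid()].
#' @param scenario a [make_scenario()] (or any list with `pct_to_hort`,
#'   `pct_to_natural`).
#' @param scheme a [landcover_scheme()].
#' @return a new `landscape_grid`.
#' @export
allocate_local <- function(grid, scenario, scheme = landcover_scheme()) {
  f_h <- scenario$pct_to_hort
  f_n <- scenario$pct_to_natural
  g <- cover_matrix(grid)
  mod <- grid$modifiable
  gr_total <- rowSums(g[, scheme$grazing, drop = FALSE])
  g[mod, scheme$grazing] <- g[mod, scheme$grazing, drop = FALSE] * (1 - f_h - f_n)
  g[mod, scheme$horticulture] <- g[mod, scheme$horticulture] + f_h * gr_total[mod]
  for (cls in scheme$natural) {
    g[mod, cls] <- g[mod, cls] + f_n * gr_total[mod] / 3
  }
  landscape_grid(g, attr(grid, "n_rows"), attr(grid, "n_cols"),
                 grid$modifiable, classes = attr(grid, "classes"))
}

#' Rank modifiable cells by expected benefit of a grazing-to-horticulture swap
#'
#' For each modifiable cell, computes the expected improvement in average
#' species occurrence per unit area exchanged: a fixed small unit (default 1
#' percentage point of the cell, taken proportionally from the grazing
#' classes, capped at the cell's grazing content) is moved into horticulture
#' and the change in masked occurrence probability at posterior-mean
#' coefficients, averaged over species and divided by the area moved, is the
#' cell's benefit. Species whose mask excludes the cell contribute 0. Cells
#' with no grazing have benefit 0 and rank last among ties.
#'
#' @param grid a [landscape_grid()].
#' @param models list of `landuse_model`s (retained species).
#' @param masks named list (by species id) of logical mask vectors matching
#'   the climate scenario under which conversion is assessed.
#' @param scheme a [landcover_scheme()].
#' @param unit_pct size of the probe exchange in percentage points of cell
#'   area (default 1).
#' @return data frame `cell_id`, `benefit`, ordered best-first (descending
#'   benefit; zero-grazing cells last among ties). Only modifiable cells are
#'   listed.
#' @export
rank_cells_by_benefit <- function(grid, models, masks,
                                  scheme = landcover_scheme(), unit_pct = 1) {
  if (length(models) == 0) stop("at least one retained species is required")
  mod_idx <- which(grid$modifiable)
  X <- cover_percent(grid)[mod_idx, , drop = FALSE]
  gr_pct <- rowSums(X[, scheme$grazing, drop = FALSE])
  a_eff <- pmin(unit_pct, gr_pct)
  X2 <- X
  scale <- ifelse(gr_pct > 0, 1 - a_eff / gr_pct, 1)
  X2[, scheme$grazing] <- X2[, scheme$grazing, drop = FALSE] * scale
  X2[, scheme$horticulture] <- X2[, scheme$horticulture] + a_eff
  benefit <- numeric(length(mod_idx))
  for (m in models) {
    msk <- masks[[m$species_id]][mod_idx]
    p1 <- plogis(drop(X %*% m$beta_mean))
    p2 <- plogis(drop(X2 %*% m$beta_mean))
    dp <- (p2 - p1) * msk
    benefit <- benefit + ifelse(a_eff > 0, dp / a_eff, 0)
  }
  benefit <- benefit / length(models)
  ord <- order(-benefit, gr_pct == 0)
  data.frame(cell_id = grid$cell_id[mod_idx][ord], benefit = benefit[ord])
}

#' Ranked (Best/Worst) allocation of grazing-land conversion
#'
#' Walks the benefit ordering converting each cell's entire grazing content
#' to the target cover until the national target area (the fraction applied
#' to the grazing stock of the modifiable cells, i.e. the same national
#' amount a local allocation exchanges) is met, with a fractional conversion
#' in the final cell.
#' Under `direction = "best"` horticulture is allocated from the top of the
#' ordering and natural covers from the bottom; `"worst"` reverses both
#' walks. Released grazing is removed proportionally from the three grazing
#' classes; natural gains are split equally among the three natural covers.
#'
#' @param grid a [landscape_grid()].
#' @param scenario a [make_scenario()].
#' @param ranking data frame from [rank_cells_by_benefit()] covering all
#'   modifiable cells.
#' @param direction `"best"` or `"worst"` (defaults to
#'   `scenario$allocation`).
#' @param scheme a [landcover_scheme()].
#' @return a new `landscape_grid`.
#' @export
allocate_ranked <- function(grid, scenario, ranking,
                            direction = scenario$allocation,
                            scheme = landcover_scheme()) {
  direction <- match.arg(direction, c("best", "worst"))
  g <- cover_matrix(grid)
  # national grazing stock of the analysis area (modifiable cells), so that
  # ranked and local allocations exchange identical national areas
  national_grazing <- sum(g[grid$modifiable, scheme$grazing])
  target_h <- scenario$pct_to_hort * national_grazing
  target_n <- scenario$pct_to_natural * national_grazing
  cells <- ranking$cell_id
  if (!setequal(cells, grid$cell_id[grid$modifiable])) {
    stop("ranking must cover exactly the modifiable cells")
  }
  hort_walk <- if (direction == "best") cells else rev(cells)
  nat_walk <- rev(hort_walk)
  avail <- setNames(rowSums(g[, scheme$grazing, drop = FALSE]), grid$cell_id)
  convert <- function(g, walk, target, gain_classes) {
    remaining <- target
    for (cid in walk) {
      if (remaining <= 1e-12) break
      take <- min(avail[[as.character(cid)]], remaining)
      if (take <= 0) next
      i <- cid  # cell_id equals row index by construction
      gr <- g[i, scheme$grazing]
      tot <- sum(gr)
      g[i, scheme$grazing] <- gr * (1 - take / tot)
      g[i, gain_classes] <- g[i, gain_classes] + take / length(gain_classes)
      avail[[as.character(cid)]] <<- avail[[as.character(cid)]] - take
      remaining <- remaining - take
    }
    if (remaining > 1e-9) {
      stop("national target exceeds available grazing in modifiable cells")
    }
    g
  }
  g <- convert(g, hort_walk, target_h, scheme$horticulture)
  g <- convert(g, nat_walk, target_n, scheme$natural)
  landscape_grid(g, attr(grid, "n_rows"), attr(grid, "n_cols"),
                 grid$modifiable, classes = attr(grid, "classes"))
}

#' Apply a scenario's allocation strategy to a landscape
#'
#' Dispatches to [allocate_local()] or [allocate_ranked()] (computing the
#' benefit ranking from the supplied models and masks when needed).
#'
#' @param grid a [landscape_grid()].
#' @param scenario a [make_scenario()].
#' @param scheme a [landcover_scheme()].
#' @param models,masks required for ranked allocations; see
#'   [rank_cells_by_benefit()].
#' @param unit_pct probe size for the benefit ranking.
#' @return a new `landscape_grid`.
#' @export
allocate_scenario <- function(grid, scenario, scheme = landcover_scheme(),
                              models = NULL, masks = NULL, unit_pct = 1) {
  if (scenario$allocation == "local") {
    allocate_local(grid, scenario, scheme)
  } else {
    if (is.null(models) || is.null(masks)) {
      stop("ranked allocation requires land-use models and climate masks")
    }
    ranking <- rank_cells_by_benefit(grid, models, masks, scheme, unit_pct)
    allocate_ranked(grid, scenario, ranking, scenario$allocation, scheme)
  }
}
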