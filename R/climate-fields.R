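#' Compute bioclimatic variables from monthly climate series
#'
#' Converts a 12-month series per cell into the four bioclim predictors used
#' by the envelope models: BIO1 mean annual temperature (mean over months of
#' `(tmax + tmin)/2`), BIO3 isothermality (`100 * bio2 / bio7`, where BIO2 is
#' the mean monthly diurnal range `tmax - tmin` and BIO7 the annual range
#' `max(tmax) - min(tmin)`; defined as 0 when BIO7 is 0), BIO12 annual
#' precipitation (sum), and BIO13 precipitation of the wettest month (max).
#'
#' @param monthly data frame with columns `cell_id`, `month` (1-12), `tmax`,
#'   `tmin`, `precip`; exactly one row per cell-month.
#' @param scenario label attached to the output field.
#' @return a [climate_field()].
#' @export
compute_bioclim <- function(monthly, scenario = "baseline") {
  needed <- c("cell_id", "month", "tmax", "tmin", "precip")
  if (!all(needed %in% names(monthly))) {
    stop("monthly climate must have columns: ", paste(needed, collapse = ", "))
  }
  counts <- table(monthly$cell_id)
  if (any(counts != 12) ||
      any(!monthly$month %in% 1:12) ||
      anyDuplicated(monthly[, c("cell_id", "month")])) {
    stop("each cell must have exactly one row for each of the 12 months")
  }
  if (any(monthly$tmax < monthly$tmin)) stop("tmax must be >= tmin")
  sp <- split(monthly, monthly$cell_id)
  ids <- as.integer(names(sp))
  stat <- vapply(sp, function(d) {
    bio1 <- mean((d$tmax + d$tmin) / 2)
    bio2 <- mean(d$tmax - d$tmin)
    bio7 <- max(d$tmax) - min(d$tmin)
    bio3 <- if (bio7 == 0) 0 else 100 * bio2 / bio7
    c(bio1, bio3, sum(d$precip), max(d$precip))
  }, numeric(4))
  o <- order(ids)
  climate_field(ids[o], scenario, stat[1, o], stat[2, o], stat[3, o], stat[4, o])
}

#' Scaling-factor (change-factor) downscaling of a coarse projection
#'
#' Transfers a coarse model's anomaly onto a fine-resolution baseline:
#' additive for temperature variables (`bio1`, `bio3`) and multiplicative for
#' precipitation variables (`bio12`, `bio13`), with the ratio defined as 1
#' where the coarse baseline is 0. `bio13` is clipped into
#' `[bio12/12, bio12]` after scaling to re-enforce the field invariants.
#'
#' @param coarse_future,coarse_baseline `climate_field`s on the coarse grid
#'   (matching `cell_id`s).
#' @param fine_baseline `climate_field` on the fine grid.
#' @param mapping data frame with columns `cell_id` (fine) and
#'   `coarse_cell_id`; every fine cell must map to exactly one coarse cell.
#' @param scenario label attached to the output field.
#' @return a `climate_field` on the fine grid.
#' @export
downscale_scaling_factor <- function(coarse_future, coarse_baseline,
                                     fine_baseline, mapping,
                                     scenario = "future") {
  idx <- match(mapping$coarse_cell_id[match(fine_baseline$cell_id, mapping$cell_id)],
               coarse_baseline$cell_id)
  if (any(is.na(idx))) stop("every fine cell must map to a coarse cell")
  fidx <- match(coarse_baseline$cell_id, coarse_future$cell_id)
  if (any(is.na(fidx))) stop("coarse future and baseline grids must match")
  cf <- coarse_future[fidx, , drop = FALSE]
  add <- function(v) fine_baseline[[v]] + (cf[[v]][idx] - coarse_baseline[[v]][idx])
  mul <- function(v) {
    ratio <- ifelse(coarse_baseline[[v]][idx] == 0, 1,
                    cf[[v]][idx] / coarse_baseline[[v]][idx])
    fine_baseline[[v]] * ratio
  }
  bio12 <- mul("bio12")
  bio13 <- pmin(pmax(mul("bio13"), bio12 / 12), bio12)
  climate_field(fine_baseline$cell_id, scenario, add("bio1"),
                pmin(pmax(add("bio3"), 0), 100), bio12, bio13)
}

#' Decadal ensemble mean across climate models
#'
#' For each climate model, averages the annual bioclim fields over the years
#' of the requested decade per cell; then takes the unweighted mean across
#' models, giving a single ensemble-mean field. The model count is not fixed.
#'
#' @param per_model_annual data frame with columns `model`, `year`, `cell_id`,
#'   `bio1`, `bio3`, `bio12`, `bio13` (one row per model-year-cell).
#' @param decade first year of the decade (e.g. `2050` means 2050-2059).
#' @param scenario label attached to the output field.
#' @return a `climate_field`.
#' @export
ensemble_decadal_mean <- function(per_model_annual, decade,
                                  scenario = sprintf("%ds", decade)) {
  d <- per_model_annual[per_model_annual$year >= decade &
                          per_model_annual$year < decade + 10, , drop = FALSE]
  if (nrow(d) == 0) stop("no model-years fall within the requested decade")
  vars <- c("bio1", "bio3", "bio12", "bio13")
  # mean over years within model, then mean over models
  per_model <- aggregate(d[, vars], by = list(model = d$model, cell_id = d$cell_id),
                         FUN = mean)
  ens <- aggregate(per_model[, vars], by = list(cell_id = per_model$cell_id),
                   FUN = mean)
  ens <- ens[order(ens$cell_id), , drop = FALSE]
  bio13 <- pmin(pmax(ens$bio13, ens$bio12 / 12), ens$bio12)
  climate_field(ens$cell_id, scenario, ens$bio1, ens$bio3, ens$bio12, bio13)
}
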