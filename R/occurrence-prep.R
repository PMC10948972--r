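#' Filter raw occurrence records
#'
#' Standardises raw presence-only records: keeps only records with a
#' day-resolved date from `min_year` onwards, spatial precision at least as
#' fine as `max_precision_m`, species-level taxon rank, and removes duplicates
#' on (species, location, date). Filtering is idempotent.
#'
#' @param records data frame with columns `species_id`, `x_1km`, `y_1km`,
#'   `date`, `spatial_precision_m`, `taxon_rank`.
#' @param min_year earliest retained year (default 1970).
#' @param max_precision_m coarsest retained precision in metres (default 1000,
#'   i.e. 1 km).
#' @return filtered data frame (possibly empty) with `date` as `Date`.
#' @export
filter_records <- function(records, min_year = 1970, max_precision_m = 1000) {
  needed <- c("species_id", "x_1km", "y_1km", "date",
              "spatial_precision_m", "taxon_rank")
  if (!all(needed %in% names(records))) {
    stop("records must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(records) == 0) {
    records$date <- as.Date(records$date)
    return(records)
  }
  d <- suppressWarnings(as.Date(records$date))
  keep <- !is.na(d) &
    as.integer(format(d, "%Y")) >= min_year &
    is.finite(records$spatial_precision_m) &
    records$spatial_precision_m > 0 &
    records$spatial_precision_m <= max_precision_m &
    records$taxon_rank == "species"
  out <- records[keep, , drop = FALSE]
  out$date <- d[keep]
  dup <- duplicated(out[, c("species_id", "x_1km", "y_1km", "date")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Map 1-km coordinates to 0-based cell row/col under the half-open convention:
# a 1-km point belongs to cell floor(coord / 2), lower-left origin.
point_to_cell <- function(x_1km, y_1km, grid) {
  row <- floor(y_1km / 2)
  col <- floor(x_1km / 2)
  inside <- row >= 0 & row < attr(grid, "n_rows") &
    col >= 0 & col < attr(grid, "n_cols")
  cell_id <- ifelse(inside, row * attr(grid, "n_cols") + col + 1, NA_integer_)
  list(cell_id = as.integer(cell_id), inside = inside)
}

#' Rarefy records to at most one presence per species per cell
#'
#' Maps each 1-km record into its enclosing 2x2 km cell (half-open cells,
#' lower-left origin: cell index `floor(coord / 2)`) and keeps each
#' (species, cell) pair once. Records falling outside the grid are excluded
#' with a warning.
#'
#' @param records filtered occurrence records (see [filter_records()]).
#' @param grid a [landscape_grid()].
#' @return data frame with columns `species_id`, `cell_id`, one row per
#'   (species, cell) presence.
#' @export
rarefy_to_cells <- function(records, grid) {
  if (nrow(records) == 0) {
    return(data.frame(species_id = character(), cell_id = integer()))
  }
  m <- point_to_cell(records$x_1km, records$y_1km, grid)
  if (any(!m$inside)) {
    warning(sprintf("%d record(s) outside grid bounds excluded", sum(!m$inside)))
  }
  out <- data.frame(species_id = records$species_id, cell_id = m$cell_id)
  out <- out[m$inside, , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out$species_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag species with enough presence cells to model
#'
#' Species with fewer than `min_records` rarefied presence cells carry too
#' little information for distribution modelling and are flagged discarded.
#'
#' @param presences data frame `species_id`, `cell_id` from
#'   [rarefy_to_cells()].
#' @param species_ids optional character vector of all candidate species (so
#'   species with zero presences appear in the output).
#' @param min_records minimum presence-cell count (default 40).
#' @return data frame `species_id`, `n_presence`, `retained`.
#' @export
check_viability <- function(presences, species_ids = NULL, min_records = 40) {
  ids <- species_ids %||% sort(unique(presences$species_id))
  n <- vapply(ids, function(s) sum(presences$species_id == s), integer(1))
  data.frame(species_id = ids, n_presence = n,
             retained = n >= min_records, row.names = NULL)
}

#' Neighbouring cells of a set of cells
#'
#' @param cells integer cell ids.
#' @param grid a [landscape_grid()].
#' @param adjacency `"queen"` (8-neighbour, default) or `"rook"`
#'   (4-neighbour).
#' @return integer vector of neighbour cell ids (excluding the input cells
#'   themselves unless they neighbour each other).
#' @export
cell_neighbors <- function(cells, grid, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  if (length(cells) == 0) return(integer())
  nr <- attr(grid, "n_rows"); nc <- attr(grid, "n_cols")
  row <- (cells - 1L) %/% nc
  col <- (cells - 1L) %% nc
  offs <- if (adjacency == "queen") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  out <- unlist(lapply(seq_len(nrow(offs)), function(i) {
    r2 <- row + offs$dr[i]; c2 <- col + offs$dc[i]
    ok <- r2 >= 0 & r2 < nr & c2 >= 0 & c2 < nc
    (r2[ok] * nc + c2[ok] + 1L)
  }))
  sort(unique(as.integer(out)))
}

# Shared pseudoabsence sampler: uniform without replacement from an eligible
# pool, with the max(floor, n_presence) count rule and pool-exhaustion capping.
sample_pa_pool <- function(presence_cells, pool, n_presence, seed,
                           floor_n = 500, species_id = "?") {
  if (length(pool) == 0) {
    stop(sprintf("no eligible pseudoabsence cells for species '%s'", species_id))
  }
  n_req <- max(floor_n, n_presence)
  if (n_req > length(pool)) {
    warning(sprintf(
      "species '%s': pseudoabsence pool exhausted (%d eligible < %d requested); capping",
      species_id, length(pool), n_req))
    n_req <- length(pool)
  }
  set.seed(seed)
  sort(pool[sample.int(length(pool), n_req)])
}

#' Sample climate-stage pseudoabsences for one species
#'
#' Samples uniformly without replacement from cells that neither contain a
#' presence nor lie within one cell (8-neighbour by default) of a presence.
#' The count is `max(floor_n, n_presence)`, capped at the eligible pool size
#' with a warning.
#'
#' @param presence_cells integer presence cell ids for the species.
#' @param grid a [landscape_grid()].
#' @param seed integer seed for the draw.
#' @param floor_n minimum pseudoabsence count (default 500).
#' @param adjacency buffer adjacency rule, see [cell_neighbors()].
#' @param species_id label used in messages.
#' @return sorted integer vector of pseudoabsence cell ids.
#' @export
sample_pseudoabsences_climate <- function(presence_cells, grid, seed,
                                          floor_n = 500,
                                          adjacency = "queen",
                                          species_id = "?") {
  excluded <- union(presence_cells,
                    cell_neighbors(presence_cells, grid, adjacency))
  pool <- setdiff(grid$cell_id, excluded)
  sample_pa_pool(presence_cells, pool, length(presence_cells), seed,
                 floor_n, species_id)
}

#' Sample land-use-stage pseudoabsences for one species
#'
#' Same exclusion and count rules as [sample_pseudoabsences_climate()], but
#' the eligible pool is further restricted to cells inside the species'
#' climatic consensus mask: a climatically suitable cell without a record is
#' interpreted as unsuitable land cover rather than unsuitable climate.
#'
#' @inheritParams sample_pseudoabsences_climate
#' @param climate_mask logical vector over grid cells (the species' consensus
#'   presence mask) or integer vector of suitable cell ids.
#' @return sorted integer vector of pseudoabsence cell ids.
#' @export
sample_pseudoabsences_landuse <- function(presence_cells, grid, climate_mask,
                                          seed, floor_n = 500,
                                          adjacency = "queen",
                                          species_id = "?") {
  suitable <- if (is.logical(climate_mask)) grid$cell_id[climate_mask]
              else as.integer(climate_mask)
  if (length(suitable) == 0) {
    stop(sprintf("species '%s': climatically suitable pool is empty", species_id))
  }
  excluded <- union(presence_cells,
                    cell_neighbors(presence_cells, grid, adjacency))
  pool <- setdiff(suitable, excluded)
  sample_pa_pool(presence_cells, pool, length(presence_cells), seed,
                 floor_n, species_id)
}
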