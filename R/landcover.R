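#' Default land-cover class names
#'
#' Names for the 24 land-cover classes used throughout the package. Three
#' classes form the grazing pool (permanent grassland, temporary grassland,
#' rough grazing), one is horticulture, and three are the natural covers that
#' receive released grazing land (semi-natural grass, farm woodland, other
#' woodland). For class counts other than 24 generic `class_XX` names are used
#' and no grazing/horticulture/natural scheme is defined.
#'
#' @param n_classes number of land-cover classes.
#' @return character vector of class names.
#' @export
lc_class_names <- function(n_classes = 24) {
  if (n_classes == 24) {
    c(
      "wheat", "barley", "oats", "oilseed_rape", "potatoes", "sugar_beet",
      "maize", "other_arable", "horticulture", "orchard",
      "permanent_grassland", "temporary_grassland", "rough_grazing",
      "seminatural_grass", "farm_woodland", "other_woodland",
      "heath_moorland", "bog", "freshwater", "coastal",
      "urban", "suburban", "bare_rock", "fallow"
    )
  } else {
    sprintf("class_%02d", seq_len(n_classes))
  }
}

#' Land-cover scheme: grazing, horticulture and natural class subsets
#'
#' Identifies, within the 24 land-cover classes, the three grazing classes
#' that scenarios draw down, the horticulture class they expand, and the three
#' natural covers that receive the remainder of released grazing land.
#'
#' @param classes character vector of class names (default [lc_class_names()]).
#' @param grazing names of the grazing classes.
#' @param horticulture name of the horticulture class.
#' @param natural names of the natural cover classes.
#' @return an object of class `landcover_scheme`.
#' @export
landcover_scheme <- function(classes = lc_class_names(24),
                             grazing = c("permanent_grassland",
                                         "temporary_grassland",
                                         "rough_grazing"),
                             horticulture = "horticulture",
                             natural = c("seminatural_grass",
                                         "farm_woodland",
                                         "other_woodland")) {
  members <- c(grazing, horticulture, natural)
  if (anyDuplicated(members)) {
    stop("grazing, horticulture and natural subsets must be disjoint")
  }
  if (!all(members %in% classes)) {
    stop("scheme subsets must be drawn from the class list")
  }
  structure(
    list(classes = classes, grazing = grazing,
         horticulture = horticulture, natural = natural),
    class = "landcover_scheme"
  )
}

#' Construct a landscape grid object
#'
#' A landscape grid is a data frame with one row per 2x2 km cell holding the
#' cell id, 0-based row/col indices, one column of cover proportion per
#' land-cover class, and a logical `modifiable` flag marking cells where land
#' use is allowed to change. Cell ids are row-major:
#' `cell_id = row * n_cols + col + 1`.
#'
#' @param cover matrix (`n_cells` x `n_classes`) of cover proportions, rows
#'   ordered by cell id.
#' @param n_rows,n_cols grid dimensions in cells.
#' @param modifiable logical vector of length `n_cells`.
#' @param classes class names (columns of `cover`).
#' @return an object of class `landscape_grid` (also a data frame).
#' @export
landscape_grid <- function(cover, n_rows, n_cols, modifiable,
                           classes = lc_class_names(ncol(cover))) {
  n <- n_rows * n_cols
  stopifnot(nrow(cover) == n, length(modifiable) == n,
            ncol(cover) == length(classes))
  sums <- rowSums(cover)
  if (any(cover < -1e-12) || any(abs(sums - 1) > 1e-9)) {
    stop("cover proportions must be non-negative and sum to 1 per cell")
  }
  df <- data.frame(
    cell_id = seq_len(n),
    row = rep(seq_len(n_rows) - 1L, each = n_cols),
    col = rep(seq_len(n_cols) - 1L, times = n_rows)
  )
  cover <- as.matrix(cover)
  colnames(cover) <- classes
  df <- cbind(df, as.data.frame(cover))
  df$modifiable <- as.logical(modifiable)
  structure(df, class = c("landscape_grid", "data.frame"),
            n_rows = n_rows, n_cols = n_cols, classes = classes)
}

#' Extract the cover matrix (proportions) from a landscape grid
#' @param grid a `landscape_grid`.
#' @return numeric matrix `n_cells` x `n_classes` of proportions.
#' @export
cover_matrix <- function(grid) {
  as.matrix(grid[, attr(grid, "classes"), drop = FALSE])
}

#' Extract the cover matrix in percentage points (0-100)
#'
#' The land-use response model is specified on covariates in percentage points
#' of cell area, which is the scale on which its unit-sd prior was elicited.
#'
#' @param grid a `landscape_grid`.
#' @return numeric matrix `n_cells` x `n_classes` of percentages.
#' @export
cover_percent <- function(grid) cover_matrix(grid) * 100

#' Number of cells in a landscape grid
#' @param grid a `landscape_grid`.
#' @return integer cell count.
#' @export
n_cells <- function(grid) nrow(grid)

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "landscape_grid: %d x %d cells (%d), %d cover classes, %.1f%% modifiable\n",
    attr(x, "n_rows"), attr(x, "n_cols"), nrow(x),
    length(attr(x, "classes")), 100 * mean(x$modifiable)
  ))
  invisible(x)
}

# Rebuild landscape_grid attributes after data-frame subsetting/IO round trips.
as_landscape_grid <- function(df, n_rows, n_cols, classes) {
  structure(as.data.frame(df), class = c("landscape_grid", "data.frame"),
            n_rows = n_rows, n_cols = n_cols, classes = classes)
}
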