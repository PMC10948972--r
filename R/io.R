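# Plain-text (tab-delimited) readers and writers for the pipeline artefacts.
# Writes are atomic: a temporary file in the target directory is renamed into
# place once complete.

write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read a landscape grid as a delimited table
#' @param grid a [landscape_grid()].
#' @param path file path (tab-delimited).
#' @return `path` (write) or a `landscape_grid` (read).
#' @export
write_landscape <- function(grid, path) {
  write_tsv_atomic(as.data.frame(grid), path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  df <- read.delim(path)
  fixed <- c("cell_id", "row", "col", "modifiable")
  classes <- setdiff(names(df), fixed)
  as_landscape_grid(df, n_rows = max(df$row) + 1L, n_cols = max(df$col) + 1L,
                    classes = classes)
}

#' Write / read climate fields as a delimited table
#' @param fields a `climate_field` or list of them.
#' @param path file path.
#' @return `path` (write) or a named list of `climate_field`s by scenario
#'   (read).
#' @export
write_climate <- function(fields, path) {
  if (inherits(fields, "climate_field")) fields <- list(fields)
  write_tsv_atomic(do.call(rbind, lapply(fields, as.data.frame)), path)
}

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  df <- read.delim(path)
  out <- lapply(split(df, df$scenario), function(d) {
    d <- d[order(d$cell_id), , drop = FALSE]
    climate_field(d$cell_id, d$scenario[1], d$bio1, d$bio3, d$bio12, d$bio13)
  })
  out
}

#' Write / read occurrence records as a delimited table
#' @param records occurrence data frame (see [sample_occurrences()]).
#' @param path file path.
#' @export
write_occurrences <- function(records, path) {
  records$date <- format(as.Date(records$date), "%Y-%m-%d")
  write_tsv_atomic(records, path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- read.delim(path, colClasses = c(species_id = "character"))
  df$date <- as.Date(df$date)
  df
}

#' Write / read virtual-species ground truth as structured text (JSON)
#' @param species list of `true_species`.
#' @param path file path.
#' @export
write_true_species <- function(species, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- lapply(species, function(sp) {
    list(species_id = sp$species_id,
         envelope_bounds = lapply(sp$envelope_bounds, unname),
         true_beta = sp$true_beta,
         thinning_prob = sp$thinning_prob)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_true_species
#' @export
read_true_species <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    structure(
      list(species_id = payload$species_id[i],
           envelope_bounds = list(
             bio1 = setNames(payload$envelope_bounds$bio1[[i]], c("lower", "upper")),
             bio12 = setNames(payload$envelope_bounds$bio12[[i]], c("lower", "upper"))),
           true_beta = payload$true_beta[[i]],
           thinning_prob = payload$thinning_prob[i]),
      class = "true_species")
  })
}

#' Write / read consensus masks as a delimited table
#'
#' One row per (species, scenario, presence cell).
#'
#' @param masks nested named list `masks[[species_id]][[scenario]]` of logical
#'   vectors.
#' @param path file path.
#' @param n_cells_total number of grid cells (needed to rebuild logical
#'   vectors on read).
#' @export
write_masks <- function(masks, path) {
  rows <- list()
  for (sp in names(masks)) {
    for (sc in names(masks[[sp]])) {
      cells <- which(masks[[sp]][[sc]])
      if (length(cells)) {
        rows[[paste(sp, sc)]] <- data.frame(species_id = sp, scenario = sc,
                                            cell_id = cells)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), scenario = character(),
               cell_id = integer())
  write_tsv_atomic(df, path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, n_cells_total) {
  df <- read.delim(path, colClasses = c(species_id = "character"))
  masks <- list()
  for (sp in unique(df$species_id)) {
    masks[[sp]] <- list()
    d_sp <- df[df$species_id == sp, , drop = FALSE]
    for (sc in unique(d_sp$scenario)) {
      v <- logical(n_cells_total)
      v[d_sp$cell_id[d_sp$scenario == sc]] <- TRUE
      masks[[sp]][[sc]] <- v
    }
  }
  masks
}

#' Write / read land-use models as a delimited table
#'
#' Stores each species' 24 posterior means, the flattened 24 x 24 posterior
#' covariance, and the evaluation AUC/threshold in one wide row.
#'
#' @param models list of `landuse_model`s.
#' @param path file path.
#' @export
write_landuse_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    p <- length(m$beta_mean)
    row <- data.frame(species_id = m$species_id, prior_sd = m$prior$sd,
                      eval_auc = m$eval_auc, threshold = m$threshold)
    means <- as.data.frame(t(m$beta_mean))
    names(means) <- sprintf("beta_%02d", seq_len(p))
    covs <- as.data.frame(t(as.vector(m$beta_cov)))
    names(covs) <- sprintf("cov_%03d", seq_len(p * p))
    cbind(row, means, covs)
  })
  write_tsv_atomic(do.call(rbind, rows), path)
}

#' @rdname write_landuse_models
#' @export
read_landuse_models <- function(path) {
  df <- read.delim(path, colClasses = c(species_id = "character"))
  beta_cols <- grep("^beta_", names(df))
  cov_cols <- grep("^cov_", names(df))
  p <- length(beta_cols)
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(species_id = df$species_id[i],
           beta_mean = as.numeric(df[i, beta_cols]),
           beta_cov = matrix(as.numeric(df[i, cov_cols]), p, p),
           prior = prior_spec(df$prior_sd[i], p),
           converged = TRUE,
           eval_auc = df$eval_auc[i], threshold = df$threshold[i]),
      class = "landuse_model")
  })
}
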