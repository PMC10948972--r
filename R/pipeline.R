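#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the study design:
#' records from 1970 at 1-km precision, a 40-record viability floor, a
#' 500-cell pseudoabsence floor, 5-fold cross-validation, a 0.6 AUC screen,
#' two-thirds envelope consensus, 7 retained land-cover PCs, a unit-sd prior,
#' a 10% gain/loss level and 10,000 posterior draws.
#'
#' The default scenario list pairs the two production-driven conversions
#' (domestic-only: 5% of grazing to horticulture and 18% to natural covers;
#' domestic/import: 2.6% and 27.4%) with a no-change comparator, under both
#' current and future climate.
#'
#' @param out_dir directory for stage artefacts.
#' @param seed integer run seed (per-stage substreams are derived from it).
#' @param synth a [synthetic_config()] describing the simulated study system.
#' @param min_year,max_precision_m record filtering rules.
#' @param min_records species viability floor.
#' @param pa_floor pseudoabsence count floor.
#' @param k_folds cross-validation folds.
#' @param auc_floor AUC screening floor.
#' @param consensus_rule envelope consensus rule.
#' @param n_pcs retained land-cover principal components.
#' @param prior_sd land-use prior standard deviation (1 or 1/6).
#' @param eval_screen logical; run the pooled mixed-model evaluation screen
#'   before the Bayesian fits.
#' @param change_level relative gain/loss threshold.
#' @param n_draws posterior draws for impact statistics.
#' @param benefit_unit_pct probe size for the Best/Worst benefit ranking.
#' @param scenarios list of [make_scenario()] objects.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("landshift_run_"),
                            seed = 1L,
                            synth = synthetic_config(seed = seed),
                            min_year = 1970, max_precision_m = 1000,
                            min_records = 40, pa_floor = 500,
                            k_folds = 5, auc_floor = 0.6,
                            consensus_rule = "two-thirds",
                            n_pcs = 7, prior_sd = 1,
                            eval_screen = TRUE,
                            change_level = 0.10, n_draws = 10000,
                            benefit_unit_pct = 1,
                            scenarios = default_scenarios()) {
  stopifnot(min_records >= 1, pa_floor >= 1, k_folds >= 2,
            auc_floor >= 0 && auc_floor <= 1, n_pcs >= 1, prior_sd > 0,
            change_level > 0, n_draws >= 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
         min_year = min_year, max_precision_m = max_precision_m,
         min_records = min_records, pa_floor = pa_floor,
         k_folds = k_folds, auc_floor = auc_floor,
         consensus_rule = consensus_rule, n_pcs = n_pcs,
         prior_sd = prior_sd, eval_screen = eval_screen,
         change_level = change_level, n_draws = n_draws,
         benefit_unit_pct = benefit_unit_pct, scenarios = scenarios),
    class = "pipeline_config"
  )
}

#' Default scenario list
#'
#' The two production-driven conversion scenarios (domestic-only and
#' domestic/import, locally allocated) and a no-change comparator, each under
#' current and future climate. Conversion fractions come from
#' [scenario_from_production()] applied to the national production-change
#' inputs (23% grazing reduction with 334% horticulture increase; 30% with
#' 123%).
#'
#' @return named list of [make_scenario()] objects.
#' @export
default_scenarios <- function() {
  do_arith <- scenario_from_production(52127, 23, 600, 334)
  di_arith <- scenario_from_production(52127, 30, 600, 123)
  list(
    no_change = make_scenario("no_change", 0, 0, "local", "baseline"),
    do_local = make_scenario("do_local", do_arith$pct_to_hort,
                             do_arith$pct_to_natural, "local", "baseline"),
    di_local = make_scenario("di_local", di_arith$pct_to_hort,
                             di_arith$pct_to_natural, "local", "baseline"),
    no_change_cc = make_scenario("no_change_cc", 0, 0, "local", "future"),
    do_local_cc = make_scenario("do_local_cc", do_arith$pct_to_hort,
                                do_arith$pct_to_natural, "local", "future"),
    di_local_cc = make_scenario("di_local_cc", di_arith$pct_to_hort,
                                di_arith$pct_to_natural, "local", "future")
  )
}

# ---- in-memory stage functions -------------------------------------------

#' Prepare occurrences: filter, rarefy, screen, sample climate pseudoabsences
#'
#' @param occurrences raw occurrence records.
#' @param grid a [landscape_grid()].
#' @param config a [pipeline_config()].
#' @return list with `presences` (species_id, cell_id), `status`
#'   (viability table), `pa_climate` (named list of pseudoabsence cell ids
#'   for retained species).
#' @export
stage_prep <- function(occurrences, grid, config) {
  recs <- filter_records(occurrences, config$min_year, config$max_precision_m)
  presences <- rarefy_to_cells(recs, grid)
  status <- check_viability(presences, min_records = config$min_records)
  retained <- status$species_id[status$retained]
  pa_climate <- lapply(setNames(retained, retained), function(sp) {
    cells <- presences$cell_id[presences$species_id == sp]
    sample_pseudoabsences_climate(
      cells, grid, seed = stream_seed(config$seed, paste0("pa_clim_", sp)),
      floor_n = config$pa_floor, species_id = sp)
  })
  list(presences = presences, status = status, pa_climate = pa_climate)
}

#' Fit climatic envelope ensembles and consensus masks for all species
#'
#' @param prep output of [stage_prep()].
#' @param climate list of `climate_field`s (`baseline`, `future`).
#' @param config a [pipeline_config()].
#' @return list with `ensembles` (retained species only), `summary` (learner
#'   table for all species), `masks` (`masks[[species]][[scenario]]`).
#' @export
stage_envelope <- function(prep, climate, config) {
  retained <- names(prep$pa_climate)
  ensembles <- list()
  summaries <- list()
  masks <- list()
  for (sp in retained) {
    pres <- prep$presences$cell_id[prep$presences$species_id == sp]
    pa <- prep$pa_climate[[sp]]
    data <- rbind(
      cbind(label = 1, climate$baseline[pres, ENVELOPE_VARS]),
      cbind(label = 0, climate$baseline[pa, ENVELOPE_VARS])
    )
    ens <- fit_climate_envelope(data, species_id = sp, k = config$k_folds,
                                auc_floor = config$auc_floor,
                                seed = stream_seed(config$seed, paste0("env_", sp)))
    summaries[[sp]] <- envelope_summary(ens)
    ens <- screen_learners(ens)
    if (!ens$retained) next
    ensembles[[sp]] <- ens
    masks[[sp]] <- lapply(climate, function(cf)
      consensus_mask(ens, cf, rule = config$consensus_rule))
  }
  list(ensembles = ensembles, summary = do.call(rbind, c(summaries,
         list(make.row.names = FALSE))), masks = masks)
}

#' Fit land-use response models for all climatically modelled species
#'
#' Samples climate-conditioned pseudoabsences inside each species' baseline
#' consensus mask, optionally runs the pooled PCA + mixed-model evaluation
#' screen, and fits the per-species Bayesian no-intercept logistic model.
#'
#' @param prep output of [stage_prep()].
#' @param envelope output of [stage_envelope()].
#' @param grid a [landscape_grid()].
#' @param config a [pipeline_config()].
#' @return list with `models` (retained species), `eval` (screen table or
#'   NULL), `pa_landuse` (named list of pseudoabsence cells).
#' @export
stage_landuse <- function(prep, envelope, grid, config) {
  sp_ids <- names(envelope$masks)
  pa_landuse <- list()
  datasets <- list()
  for (sp in sp_ids) {
    pres <- prep$presences$cell_id[prep$presences$species_id == sp]
    pa <- tryCatch(
      sample_pseudoabsences_landuse(
        pres, grid, envelope$masks[[sp]]$baseline,
        seed = stream_seed(config$seed, paste0("pa_lu_", sp)),
        floor_n = config$pa_floor, species_id = sp),
      error = function(e) NULL)
    if (is.null(pa)) next
    pa_landuse[[sp]] <- pa
    datasets[[sp]] <- data.frame(species_id = sp,
                                 cell_id = c(pres, pa),
                                 label = rep(c(1, 0), c(length(pres), length(pa))))
  }
  if (length(datasets) == 0) stop("no species eligible for land-use modelling")
  pooled <- do.call(rbind, c(datasets, list(make.row.names = FALSE)))
  eval_tab <- NULL
  retained <- names(datasets)
  if (isTRUE(config$eval_screen)) {
    pca <- pca_landcover(grid, n_retained = config$n_pcs)
    scores <- pca_scores(pca, grid)
    pooled_pcs <- cbind(pooled, scores[pooled$cell_id, , drop = FALSE])
    eval_tab <- fit_eval_mixed_model(pooled_pcs, k = config$k_folds,
                                     seed = stream_seed(config$seed, "eval_mm"),
                                     auc_floor = config$auc_floor)
    retained <- eval_tab$species_id[eval_tab$retained]
    if (length(retained) == 0) stop("evaluation screen eliminated every species")
  }
  X <- cover_percent(grid)
  models <- lapply(setNames(retained, retained), function(sp) {
    d <- datasets[[sp]]
    m <- fit_bayes_landuse(d$label, X[d$cell_id, , drop = FALSE],
                           prior = prior_spec(config$prior_sd,
                                              ncol(X)),
                           species_id = sp)
    if (!is.null(eval_tab)) {
      i <- match(sp, eval_tab$species_id)
      m$eval_auc <- eval_tab$eval_auc[i]
      m$threshold <- eval_tab$threshold[i]
    }
    m
  })
  list(models = models, eval = eval_tab, pa_landuse = pa_landuse)
}

#' Allocate land cover for every configured scenario
#'
#' @param grid baseline [landscape_grid()].
#' @param models list of `landuse_model`s (needed for ranked allocations).
#' @param masks nested mask list from [stage_envelope()].
#' @param config a [pipeline_config()].
#' @return named list of `landscape_grid`s, one per scenario.
#' @export
stage_scenario <- function(grid, models, masks, config) {
  scheme <- landcover_scheme(attr(grid, "classes"))
  lapply(config$scenarios, function(sc) {
    climate_masks <- lapply(masks, `[[`, sc$climate)
    allocate_scenario(grid, sc, scheme, models = models,
                      masks = climate_masks, unit_pct = config$benefit_unit_pct)
  })
}

#' Impact statistics for every configured scenario
#'
#' @param models list of `landuse_model`s.
#' @param grid baseline [landscape_grid()].
#' @param scenario_grids named list from [stage_scenario()].
#' @param masks nested mask list from [stage_envelope()].
#' @param config a [pipeline_config()].
#' @return list with `summary` (one row per scenario) and `impacts` (named
#'   list of `impact_summary` objects).
#' @export
stage_assess <- function(models, grid, scenario_grids, masks, config) {
  impacts <- list()
  rows <- list()
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    masks_scen <- lapply(masks, `[[`, sc$climate)
    masks_base <- lapply(masks, `[[`, sc$ref_climate)
    imp <- assess_impacts(models, grid, scenario_grids[[nm]],
                          masks_base, masks_scen,
                          change_level = config$change_level,
                          n_draws = config$n_draws,
                          seed = stream_seed(config$seed, paste0("assess_", nm)))
    impacts[[nm]] <- imp
    rows[[nm]] <- cbind(scenario = nm, climate = sc$climate,
                        pct_to_hort = sc$pct_to_hort,
                        pct_to_natural = sc$pct_to_natural,
                        allocation = sc$allocation, imp$summary)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       impacts = impacts)
}

# ---- disk-backed runner ---------------------------------------------------

stage_paths <- function(config) {
  d <- config$out_dir
  list(
    landscape = file.path(d, "landscape.tsv"),
    climate = file.path(d, "climate.tsv"),
    occurrences = file.path(d, "occurrences.tsv"),
    truth = file.path(d, "true_species.json"),
    presences = file.path(d, "presences.tsv"),
    status = file.path(d, "species_status.tsv"),
    pa_climate = file.path(d, "pa_climate.tsv"),
    envelope = file.path(d, "envelope_summary.tsv"),
    masks = file.path(d, "masks.tsv"),
    eval = file.path(d, "landuse_eval.tsv"),
    models = file.path(d, "landuse_models.tsv"),
    scenario_dir = file.path(d, "scenario_grids"),
    impact_species = file.path(d, "impact_species.tsv"),
    impact_summary = file.path(d, "impact_summary.tsv"),
    manifest = file.path(d, "manifest.json")
  )
}

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artefact '%s': run stage '%s' first",
                 basename(path), producing_stage), call. = FALSE)
  }
}

pa_list_to_df <- function(pa, stage) {
  if (length(pa) == 0) {
    return(data.frame(species_id = character(), cell_id = integer(),
                      label = character(), stage = character()))
  }
  do.call(rbind, lapply(names(pa), function(sp) {
    data.frame(species_id = sp, cell_id = pa[[sp]],
               label = "pseudoabsence", stage = stage)
  }))
}

#' Run one pipeline stage against on-disk artefacts
#'
#' Stages: `simulate` (synthetic landscape, climate, species, records),
#' `prep` (filter/rarefy/screen + climate pseudoabsences), `envelope`
#' (ensemble fits and consensus masks), `landuse` (PCA screen + Bayesian
#' models), `scenario` (land-cover allocation per scenario), `assess`
#' (impact statistics). Each stage reads its upstream artefacts from
#' `config$out_dir`, errors with the name of the producing stage when one is
#' missing, and writes its outputs atomically.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage's in-memory result, invisibly.
#' @export
run_stage <- function(name, config) {
  name <- match.arg(name, c("simulate", "prep", "envelope", "landuse",
                            "scenario", "assess"))
  p <- stage_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- switch(name,
    simulate = {
      sim <- simulate_study(config$synth)
      write_landscape(sim$grid, p$landscape)
      write_climate(sim$climate, p$climate)
      write_occurrences(sim$occurrences, p$occurrences)
      write_true_species(sim$species, p$truth)
      sim
    },
    prep = {
      require_artifact(p$occurrences, "simulate")
      require_artifact(p$landscape, "simulate")
      grid <- read_landscape(p$landscape)
      prep <- stage_prep(read_occurrences(p$occurrences), grid, config)
      write_tsv_atomic(prep$presences, p$presences)
      write_tsv_atomic(prep$status, p$status)
      write_tsv_atomic(pa_list_to_df(prep$pa_climate, "climate"), p$pa_climate)
      prep
    },
    envelope = {
      require_artifact(p$presences, "prep")
      require_artifact(p$climate, "simulate")
      grid <- read_landscape(p$landscape)
      prep <- read_prep(config)
      climate <- read_climate(p$climate)
      env <- stage_envelope(prep, climate, config)
      write_tsv_atomic(env$summary, p$envelope)
      write_masks(env$masks, p$masks)
      env
    },
    landuse = {
      require_artifact(p$masks, "envelope")
      require_artifact(p$presences, "prep")
      grid <- read_landscape(p$landscape)
      prep <- read_prep(config)
      envelope <- list(masks = read_masks(p$masks, nrow(grid)))
      lu <- stage_landuse(prep, envelope, grid, config)
      if (!is.null(lu$eval)) write_tsv_atomic(lu$eval, p$eval)
      write_landuse_models(lu$models, p$models)
      lu
    },
    scenario = {
      require_artifact(p$models, "landuse")
      require_artifact(p$masks, "envelope")
      grid <- read_landscape(p$landscape)
      models <- read_landuse_models(p$models)
      names(models) <- vapply(models, `[[`, character(1), "species_id")
      masks <- read_masks(p$masks, nrow(grid))
      grids <- stage_scenario(grid, models, masks, config)
      for (nm in names(grids)) {
        write_landscape(grids[[nm]], file.path(p$scenario_dir, paste0(nm, ".tsv")))
      }
      grids
    },
    assess = {
      require_artifact(p$models, "landuse")
      require_artifact(p$masks, "envelope")
      grid <- read_landscape(p$landscape)
      sc_paths <- file.path(p$scenario_dir,
                            paste0(names(config$scenarios), ".tsv"))
      for (sp in sc_paths) require_artifact(sp, "scenario")
      models <- read_landuse_models(p$models)
      names(models) <- vapply(models, `[[`, character(1), "species_id")
      masks <- read_masks(p$masks, nrow(grid))
      grids <- lapply(setNames(sc_paths, names(config$scenarios)), read_landscape)
      res <- stage_assess(models, grid, grids, masks, config)
      sp_tab <- do.call(rbind, lapply(names(res$impacts), function(nm) {
        cbind(scenario = nm, res$impacts[[nm]]$species)
      }))
      write_tsv_atomic(sp_tab, p$impact_species)
      write_tsv_atomic(res$summary, p$impact_summary)
      res
    }
  )
  write_manifest(config, name)
  invisible(result)
}

read_prep <- function(config) {
  p <- stage_paths(config)
  presences <- read.delim(p$presences, colClasses = c(species_id = "character"))
  pa <- read.delim(p$pa_climate, colClasses = c(species_id = "character"))
  pa_climate <- lapply(split(pa$cell_id, pa$species_id), as.integer)
  list(presences = presences,
       status = read.delim(p$status, colClasses = c(species_id = "character")),
       pa_climate = pa_climate)
}

write_manifest <- function(config, last_stage) {
  p <- stage_paths(config)
  cfg_txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  existing <- Filter(file.exists, unlist(p[setdiff(names(p), c("manifest",
                                                               "scenario_dir"))]))
  counts <- vapply(existing, function(f) length(readLines(f, warn = FALSE)) - 1L,
                   integer(1))
  jsonlite::write_json(
    list(seed = config$seed, last_stage = last_stage,
         config_hash = sprintf("%08x", sum(utf8ToInt(cfg_txt) *
                                             (seq_along(utf8ToInt(cfg_txt)) %% 97 + 1)) %% 4294967291),
         artefact_rows = as.list(counts),
         timestamp_free = TRUE),
    p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(p$manifest)
}

#' Run the full pipeline
#'
#' Executes simulate, prep, envelope, landuse, scenario and assess in order,
#' writing every stage artefact under `config$out_dir`. Re-running with an
#' identical configuration and seed reproduces bit-identical artefacts.
#'
#' @param config a [pipeline_config()].
#' @return the assessment result (summary table + per-scenario
#'   `impact_summary` objects), invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  for (st in c("simulate", "prep", "envelope", "landuse", "scenario")) {
    run_stage(st, config)
  }
  run_stage("assess", config)
}
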