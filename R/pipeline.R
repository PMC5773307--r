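#' Read and write point / EVI tables
#'
#' Plain-CSV exchange of presence records (id, x, y, year) and EVI
#' observations (location_id, date ISO-8601, evi, qa_rank).
#'
#' @param presences,series_list objects to write.
#' @param path file path.
#' @return the read functions return the corresponding objects.
#' @export
write_presences_csv <- function(presences, path) {
  utils::write.csv(presences[, c("id", "x", "y", "year")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_presences_csv
#' @export
read_presences_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("PresenceSet", "data.frame")
  out
}

#' @rdname write_presences_csv
#' @export
write_evi_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s)
    data.frame(location_id = s$location_id, date = format(s$dates),
               evi = s$values, qa_rank = s$qa)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presences_csv
#' @export
read_evi_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$location_id), function(g)
    evi_series(as.Date(g$date), g$evi, g$qa_rank, g$location_id[1L]))
}

#' Default pipeline configuration
#'
#' The demo profile: a 50 x 50 coarse (1 km analog) grid refined 4x to
#' the 250 m analog, 88 presence records split 75/25 five times, the
#' three candidate formulas (full, climate-only, TREE + AI), a 90 x 3
#' ground-truth design with 79 discards, and a few-hundred-tree forest.
#' The field-scale profile differs only in `classify$n_trees = 50000`
#' (slow) and larger grids.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synth = list(coarse_shape = c(50L, 50L), refine_factor = 4L,
                 n_presences = 88L, n_points = 90L, stops = 3L,
                 spacing = 500, n_discard = 79L),
    studyarea = list(elev = c(200, 1500), tree = c(10, 84),
                     ai = c(2000, 6500)),
    occurrence = list(frac = 0.75, n_replicates = 5L, n_pseudoabsences = 88L,
                      n_selected = 3L,
                      skewed = c("TREE", "BIO03", "BIO10", "BIO17", "BIO19"),
                      formulas = list(
                        mdl1 = c("TREE", "AI", "BIO02", "BIO03", "BIO07",
                                 "BIO10", "BIO17", "BIO19"),
                        mdl2 = c("BIO02", "BIO03", "BIO07", "BIO10",
                                 "BIO17", "BIO19"),
                        mdl3 = c("TREE", "AI"))),
    evi = list(min_seg = 4L, penalty = "mbic"),
    classify = list(n_trees = 300L, mtry = 5L),
    keyhab = list(t_psi = NULL, included = "excellent")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

# 23 fine-grid EVI layers for one "current" year, consistent with the
# suitability implied by the fine covariates (the analog of a 2014 EVI
# composite stack).
simulate_evi_stack <- function(landscape, baselines, degradation,
                               amplitude = 0.05, noise_sd = 0.02, seed = 1L) {
  elev <- landscape$fine_layers$ELEV
  tree <- landscape$fine_layers$TREE
  lab <- as.integer(label_from_covariates(as.vector(elev$values),
                                          as.vector(tree$values)))
  base <- (baselines - degradation)[lab]
  doy <- 1L + 16L * (0:22)
  with_seed(seed, {
    layers <- lapply(seq_len(23L), function(k) {
      v <- base + amplitude * sin(2 * pi * (doy[k] - 49) / 365) +
        rnorm(length(base), 0, noise_sd)
      grid_layer(matrix(pmin(pmax(v, 0), 1), nrow(elev$values),
                        ncol(elev$values)),
                 elev$cell_size, elev$origin, elev$nodata)
    })
  })
  layers
}

#' Run the full key-habitat pipeline
#'
#' Executes the stages in dependency order — synthetic data, study-area
#' delineation, occurrence modelling (replicated MaxLike fits, AICc model
#' selection, evaluation, threshold selection, fine-grid prediction), EVI
#' quality filtering + change-point detection + phenology, suitability
#' classification, and key-habitat delineation — writing artifacts and an
#' md5 manifest under `out_dir`. Deterministic given `config$seed`.
#'
#' @param config configuration list (see [default_config()]) or a YAML
#'   file path.
#' @param out_dir output directory (created).
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly a list with every stage's in-memory
#'   result and the artifact table).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("keyhab_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character()
  emit <- function(path) { artifacts[length(artifacts) + 1L] <<- path; path }
  seed <- config$seed

  say("[synth] generating landscape (seed %d)", seed)
  land <- generate_landscape(seed = seed,
                             coarse_shape = config$synth$coarse_shape,
                             refine_factor = config$synth$refine_factor)
  say("[studyarea] delineating study area")
  bounds <- list(ELEV = config$studyarea$elev, TREE = config$studyarea$tree,
                 AI = config$studyarea$ai)
  mask <- delineate_study_area(land$layers, bounds,
                               target_cell = land$coarse_cell)
  if (area_km2(mask) == 0) stop("[studyarea] empty study area", call. = FALSE)
  fine_mask <- delineate_study_area(land$fine_layers, bounds,
                                    target_cell = land$fine_cell)
  write_ascii_grid(mask, emit(file.path(out_dir, "study_area.asc")))

  presences <- simulate_presences(land, config$synth$n_presences,
                                  seed = seed + 1L, mask = mask)
  write_presences_csv(presences, emit(file.path(out_dir, "presences.csv")))

  design <- simulate_ground_truth(land, config$synth$n_points,
                                  config$synth$stops, config$synth$spacing,
                                  config$synth$n_discard, mask = mask,
                                  seed = seed + 2L)
  series <- simulate_evi(design, seed = seed + 3L)
  write_evi_csv(series, emit(file.path(out_dir, "evi_series.csv")))

  say("[occurrence] fitting %d formulas x %d replicates",
      length(config$occurrence$formulas), config$occurrence$n_replicates)
  skewed <- intersect(config$occurrence$skewed, names(land$layers))
  stack <- transform_and_standardize(land$layers, skewed, mask)
  splits <- partition_records(presences, config$occurrence$frac,
                              config$occurrence$n_replicates, seed = seed + 4L)
  fits <- fit_replicates(splits, stack, config$occurrence$formulas)
  best <- select_best_model(fits)
  say("[occurrence] selected: %s", paste(best$formula, collapse = " + "))
  pseudo <- sample_pseudoabsences(mask, config$occurrence$n_pseudoabsences,
                                  seed = seed + 5L)
  best_fits <- Filter(function(f)
    identical(f$formula, best$formula) && f$converged, fits)
  metrics <- lapply(best_fits, function(f)
    evaluate_fit(f, splits[[f$replicate_id]]$validation, pseudo, stack))
  chosen <- rank_replicates(metrics)[seq_len(min(config$occurrence$n_selected,
                                                 length(metrics)))]
  thr <- select_threshold(metrics, chosen)
  t_psi <- config$keyhab$t_psi %||% thr$t_psi
  say("[occurrence] t_psi = %.3f (replicates %s)", t_psi,
      paste(chosen, collapse = ","))
  fine_stack <- standardize_like(stack, land$fine_layers)
  psi_layers <- lapply(best_fits[match(chosen,
                                       vapply(best_fits, `[[`, 0L, "replicate_id"))],
                       predict_psi_surface, stack = fine_stack)
  psi <- grid_layer(Reduce(`+`, lapply(psi_layers, `[[`, "values")) /
                      length(psi_layers),
                    psi_layers[[1]]$cell_size, psi_layers[[1]]$origin)
  psi$values[fine_mask$values == 0] <- NA
  write_ascii_grid(psi, emit(file.path(out_dir, "psi_historic.asc")))

  say("[evi] change-point detection at %d locations", length(series))
  filtered <- lapply(series, filter_by_qa)
  cps <- lapply(filtered, detect_changepoint, min_seg = config$evi$min_seg,
                penalty = config$evi$penalty)
  degr <- summarize_degradation(cps, design$locations$label)
  say("[evi] %.0f%% of locations degraded", degr$pct_reduced)
  phen <- t(vapply(seq_along(filtered), function(k)
    as.numeric(phenology(filtered[[k]], cps[[k]])), numeric(23L)))

  say("[classify] fitting forest (%d trees)", config$classify$n_trees)
  forest <- fit_forest(phen, design$locations$label,
                       n_trees = config$classify$n_trees,
                       mtry = config$classify$mtry, seed = seed + 6L)
  oob <- weighted_oob(forest$oob_confusion)
  say("[classify] OOB error raw %.1f%%, weighted %.1f%%",
      100 * oob$raw_error, 100 * oob$weighted_error)
  evi_stack <- simulate_evi_stack(land,
                                  baselines = c(poor = 0.35, acceptable = 0.45,
                                                good = 0.55, excellent = 0.62),
                                  degradation = c(poor = 0.10, acceptable = 0.10,
                                                  good = 0.10, excellent = 0.10),
                                  seed = seed + 7L)
  suit <- predict_suitability(forest, evi_stack)
  suit$category$values[fine_mask$values == 0] <- NA
  suit$index$values[fine_mask$values == 0] <- NA
  write_ascii_grid(suit$category, emit(file.path(out_dir, "suitability_category.asc")))
  write_ascii_grid(suit$index, emit(file.path(out_dir, "suitability_index.asc")))

  say("[keyhab] delineating key habitats")
  report <- key_habitat_report(psi, suit$category, suit$index, t_psi)
  write_ascii_grid(report$overlap, emit(file.path(out_dir, "overlap_index.asc")))
  write_ascii_grid(report$masks$key, emit(file.path(out_dir, "key_habitat.asc")))
  rep_json <- list(t_psi = t_psi,
                   aoo_key_km2 = report$aoo_key_km2,
                   aoo_expanded_km2 = report$aoo_expanded_km2,
                   historic_km2 = report$historic_km2,
                   decline_strict = report$decline_strict,
                   decline_expanded = report$decline_expanded,
                   oob_error_raw = oob$raw_error,
                   oob_error_weighted = oob$weighted_error,
                   pct_locations_degraded = degr$pct_reduced)
  jsonlite::write_json(rep_json, emit(file.path(out_dir, "report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  say("done: %s", out_dir)
  invisible(list(out_dir = out_dir, manifest = manifest, landscape = land,
                 mask = mask, stack = stack, fits = fits, best = best,
                 metrics = metrics, threshold = thr, psi = psi,
                 design = design, changepoints = cps, degradation = degr,
                 forest = forest, oob = oob, suitability = suit,
                 report = report))
}
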