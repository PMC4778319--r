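#' Default pipeline configuration
#'
#' Nested list describing a full synthetic study: grid and voxel size,
#' phantom model, tilt geometry, photon noise, reconstruction,
#' segmentation and statistics parameters, conditions, cells per condition
#' and the master seed. The desk-scale default images a 13.4 x 13.4 x 5.0 um
#' field of view at 105 nm voxels, five cells for each of the five
#' incubation conditions. Serializable to YAML via [write_pipeline_config()].
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it via [derive_seed()].
#' @param output_dir where [run_pipeline()] writes its report bundle.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1, output_dir = tempfile("scvtomo_run_")) {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    grid = list(nx = 128L, ny = 128L, nz = 48L, voxel_size_nm = 105),
    phantom = list(background_lac = 0.30, nucleus_lac = 0.40,
                   contrast_ratio = 3,
                   nucleus_semi_axes_nm = c(2200, 1800, 1100)),
    geometry = list(start_deg = -70, stop_deg = 70, step_deg = 1),
    noise = list(photon_budget = 5000, min_counts = 0.5),
    reconstruction = list(iterations = 30L, relaxation = 1.0),
    segmentation = list(threshold_mode = "otsu_top_decile",
                        min_diameter_nm = 100, connectivity = 26L),
    stats = list(cell_diameter_um = 20, cell_thickness_um = 5),
    conditions = scv_conditions(),
    n_cells_per_condition = 5L,
    save_volumes = FALSE
  ), class = "pipeline_config")
}

required_config_fields <- c("seed", "output_dir", "grid", "phantom", "geometry",
                            "noise", "reconstruction", "segmentation", "stats",
                            "conditions", "n_cells_per_condition")

#' Validate a pipeline configuration
#'
#' Checks that every required field is present and well-formed; raises a
#' `scv_config_error` naming the first missing or invalid field.
#'
#' @param config a pipeline configuration list.
#' @return the validated config (with conditions coerced to a data frame),
#'   invisibly classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  for (f in required_config_fields)
    if (is.null(config[[f]]))
      stop_config(paste0("missing config field: ", f))
  g <- config$grid
  for (f in c("nx", "ny", "nz", "voxel_size_nm"))
    if (is.null(g[[f]]) || g[[f]] <= 0)
      stop_config(paste0("missing or invalid config field: grid$", f))
  if (is.null(config$geometry$step_deg) || config$geometry$step_deg <= 0)
    stop_config("missing or invalid config field: geometry$step_deg")
  if (!is.data.frame(config$conditions))
    config$conditions <- as.data.frame(do.call(rbind, lapply(config$conditions, as.data.frame)))
  need <- c("condition", "n_mean", "diameter_mean_nm", "diameter_sd_nm",
            "min_separation_nm", "shell_min_nm", "shell_max_nm")
  miss <- setdiff(need, names(config$conditions))
  if (length(miss))
    stop_config(paste0("missing config field: conditions$", miss[1]))
  class(config) <- unique(c("pipeline_config", class(config)))
  invisible(config)
}

stop_config <- function(msg) {
  stop(structure(class = c("scv_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$conditions, "default")) cfg$conditions <- scv_conditions()
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$conditions <- lapply(seq_len(nrow(as.data.frame(cfg$conditions))),
                           function(i) as.list(as.data.frame(cfg$conditions)[i, ]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# simulate one cell and push it through imaging, reconstruction and
# segmentation; returns truth and recovered vesicle tables plus volumes
process_cell <- function(cond, cell_idx, config, keep_volumes = FALSE) {
  g <- config$grid
  extent <- c(g$nx, g$ny, g$nz) * g$voxel_size_nm
  cell_seed <- derive_seed(config$seed, match(cond$condition,
                                              config$conditions$condition),
                           cell_idx)
  nuc_jit <- run_seeded(derive_seed(cell_seed, 9), function()
    stats::runif(3, 0.95, 1.05))
  nucleus <- nucleus_model(extent / 2,
                           config$phantom$nucleus_semi_axes_nm * nuc_jit,
                           lac = config$phantom$nucleus_lac)
  phantom <- generate_cell_phantom(
    cond, extent, nucleus = nucleus,
    background_lac = config$phantom$background_lac,
    contrast_ratio = config$phantom$contrast_ratio,
    seed = cell_seed)
  vol <- voxelize_phantom(phantom, g$voxel_size_nm)
  mask <- voxelize_nucleus_mask(phantom, g$voxel_size_nm)
  geom <- make_tilt_geometry(config$geometry$start_deg, config$geometry$stop_deg,
                             config$geometry$step_deg, g$voxel_size_nm)
  budget <- config$noise$photon_budget
  if (is.null(budget) || identical(budget, "Inf")) budget <- Inf
  series <- project_tilt_series(vol, geom, photon_budget = budget,
                                seed = derive_seed(cell_seed, 4))
  absorb <- normalize_flatfield(series,
    min_counts = if (is.finite(budget)) config$noise$min_counts else NULL)
  recon <- reconstruct_sirt(absorb, geom, dim = c(g$nx, g$ny, g$nz),
                            iterations = config$reconstruction$iterations,
                            relaxation = config$reconstruction$relaxation)
  seg <- segment_vesicles(recon, segmentation_params(
    threshold_mode = config$segmentation$threshold_mode,
    min_diameter_nm = config$segmentation$min_diameter_nm,
    connectivity = config$segmentation$connectivity),
    exclude_mask = mask)
  truth <- annotate_vesicles(phantom$vesicles, mask)
  rec <- annotate_vesicles(seg$vesicles, mask)
  truth$condition <- rep(cond$condition, nrow(truth))
  truth$cell <- rep(cell_idx, nrow(truth))
  rec$condition <- rep(cond$condition, nrow(rec))
  rec$cell <- rep(cell_idx, nrow(rec))
  out <- list(phantom = phantom, truth = truth, recovered = rec,
              threshold = seg$threshold, seed = cell_seed,
              residuals = sirt_residuals(recon))
  if (keep_volumes) {
    out$volume <- vol; out$reconstruction <- recon
    out$nucleus_mask <- mask; out$labels <- seg$labels
  }
  out
}

#' Run the full synthetic study pipeline
#'
#' For every condition and cell: generate a phantom, simulate and normalize
#' the tilt series, reconstruct with SIRT, segment vesicles and compute the
#' per-cell statistics. Writes a report bundle to `config$output_dir`:
#' per-cell ground-truth and recovered vesicle CSVs, the per-cell summary
#' table, the pooled per-condition statistics table, the per-condition
#' accumulated-volume table, a size-class point cloud
#' (`x,y,z,diameter,class`) for external renderers, the resolved YAML config
#' and a log of every stage. All outputs are deterministic for a fixed
#' master seed.
#'
#' @param config a pipeline configuration (see [default_pipeline_config()]);
#'   validated on entry.
#' @param verbose print stage progress to stderr.
#' @return (invisibly) a list with `cell_summaries`, `condition_aggregate`,
#'   `condition_table`, `volume_table`, `truth`, `recovered`, `output_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), verbose = TRUE) {
  config <- validate_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE)
    if (verbose) message(msg)
  }
  write_pipeline_config(config, file.path(config$output_dir, "config.yaml"))
  log_line("scvtomo %s, master seed %d",
           as.character(utils::packageVersion("scvtomo")), config$seed)
  cell_vol <- cell_volume_model(config$stats$cell_diameter_um,
                                config$stats$cell_thickness_um)
  summaries <- list(); truth_all <- list(); rec_all <- list()
  conds <- config$conditions
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    for (cell in seq_len(config$n_cells_per_condition)) {
      res <- process_cell(cond, cell, config,
                          keep_volumes = isTRUE(config$save_volumes))
      log_line("condition %s cell %d: %d vesicles placed, %d recovered (threshold %.3f)",
               cond$condition, cell, nrow(res$truth), nrow(res$recovered),
               res$threshold)
      tag <- sprintf("%s_cell%d", cond$condition, cell)
      write_vesicle_truth(res$phantom,
                          file.path(config$output_dir, paste0("truth_", tag, ".csv")))
      write_vesicle_set(res$recovered,
                        file.path(config$output_dir, paste0("vesicles_", tag, ".csv")))
      if (isTRUE(config$save_volumes))
        write_mrc(res$reconstruction,
                  file.path(config$output_dir, paste0("recon_", tag, ".mrc")))
      s <- summarize_cell(res$recovered, condition = cond$condition,
                          cell_volume_um3 = cell_vol)
      s$cell <- cell
      summaries[[length(summaries) + 1L]] <- s
      truth_all[[length(truth_all) + 1L]] <- res$truth
      rec_all[[length(rec_all) + 1L]] <- res$recovered
    }
  }
  cell_summaries <- do.call(rbind, summaries)
  rec_df <- do.call(rbind, rec_all)
  truth_df <- do.call(rbind, truth_all)
  cond_agg <- do.call(rbind, lapply(split(cell_summaries,
                                          cell_summaries$condition),
                                    aggregate_condition))
  cond_tab <- condition_table(rec_df)
  volume_tab <- do.call(rbind, lapply(split(cell_summaries,
                                            cell_summaries$condition),
    function(s) data.frame(condition = s$condition[1],
                           accumulated_volume_um3 = mean(s$accumulated_volume_um3),
                           volume_fraction_pct = mean(s$volume_fraction_pct))))
  ord <- match(conds$condition, cond_agg$condition)
  cond_agg <- cond_agg[ord[!is.na(ord)], ]
  volume_tab <- volume_tab[match(conds$condition, volume_tab$condition), ]
  utils::write.csv(cell_summaries,
                   file.path(config$output_dir, "cell_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(cond_agg,
                   file.path(config$output_dir, "condition_aggregate.csv"),
                   row.names = FALSE)
  utils::write.csv(cond_tab,
                   file.path(config$output_dir, "condition_table.csv"),
                   row.names = FALSE)
  utils::write.csv(volume_tab,
                   file.path(config$output_dir, "accumulated_volume.csv"),
                   row.names = FALSE)
  cloud <- rec_df[, c("condition", "cell", "x_nm", "y_nm", "z_nm",
                      "diameter_nm", "size_class")]
  utils::write.csv(cloud, file.path(config$output_dir, "size_class_cloud.csv"),
                   row.names = FALSE)
  log_line("report bundle written to %s", config$output_dir)
  invisible(list(cell_summaries = cell_summaries,
                 condition_aggregate = cond_agg,
                 condition_table = cond_tab,
                 volume_table = volume_tab,
                 truth = truth_df, recovered = rec_df,
                 output_dir = config$output_dir))
}
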