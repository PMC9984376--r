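# Pipeline orchestration: simulate -> segment -> fit -> FLIRR -> spatial ->
# report for a grid of experimental conditions (cell line x collagen
# density x day), each with replicate samples. All randomness flows from
# the single config seed; a rerun with the same config writes byte-identical
# CSV/JSON analysis outputs.

#' Default pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. The
#' defaults encode the acquisition geometry the pipeline targets
#' (0.8 um/pixel, 256 temporal bins over a 12.5 ns repetition period,
#' Gaussian IRFs of 339/396 ps FWHM for NAD(P)H/FAD) scaled to a
#' desk-size simulated field, with the standard two-condition comparison
#' layout (n = 3 replicate samples per condition, FLIRR pooled across
#' replicates).
#'
#' @param seed global integer seed.
#' @param image list: `size` (px), `pixel_size_um`, `n_bins`, `period_ns`.
#' @param irf list: `nadh_fwhm_ps`, `fad_fwhm_ps`, `center_bin`; or file
#'   paths `nadh_csv` / `fad_csv` to measured profiles.
#' @param phantom list: `photons_per_pixel`, `dark_rate`, `n_replicates`.
#' @param conditions list of condition specs; each has `label`, `cell_line`,
#'   `collagen_mg_ml`, `day`, `scene_kind`, `radius_px`, `n_blobs`,
#'   `nadh_gradient`, `fad_gradient` (see [make_phantom()]).
#' @param segmentation list of pipeline parameters.
#' @param fit list: `window`, `t_out`, `n_restarts`, `stride`.
#' @param flirr list: `grid_from`, `grid_to`, `grid_by`, `eps`.
#' @param spatial list: `edge_bin_um`, `core_from_um`, `center_bin_um`.
#' @param comparisons list of `c(label_a, label_b)` pairs to compare.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            image = list(),
                            irf = list(),
                            phantom = list(),
                            conditions = NULL,
                            segmentation = list(),
                            fit = list(),
                            flirr = list(),
                            spatial = list(),
                            comparisons = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    image = modifyList(list(size = 96L, pixel_size_um = 3.2, n_bins = 256L,
                            period_ns = 12.5), image),
    irf = modifyList(list(nadh_fwhm_ps = 339, fad_fwhm_ps = 396,
                          center_bin = 16L, nadh_csv = NULL, fad_csv = NULL),
                     irf),
    phantom = modifyList(list(photons_per_pixel = 50, dark_rate = 0,
                              n_replicates = 3L), phantom),
    conditions = conditions,
    segmentation = modifyList(list(dilate_radius_px = 3L,
                                   tophat_radius_px = 15L,
                                   sensitivity = 0.5), segmentation),
    fit = modifyList(list(window = 20L, t_out = 64L, n_restarts = 5L,
                          stride = 1L, model_grid = "native"), fit),
    flirr = modifyList(list(grid_from = 0.2, grid_to = 1.3, grid_by = 0.01,
                            eps = 1e-6), flirr),
    spatial = modifyList(list(edge_bin_um = 15, core_from_um = 75,
                              center_bin_um = 125), spatial),
    comparisons = comparisons)
  if (is.null(cfg$conditions)) {
    day0 <- list(alpha2 = c(edge = 0.65, core = 0.45),
                 tau1 = c(edge = 0.4, core = 0.4),
                 tau2 = c(edge = 2.5, core = 2.5))
    day3 <- list(alpha2 = c(edge = 0.75, core = 0.6),
                 tau1 = c(edge = 0.4, core = 0.4),
                 tau2 = c(edge = 2.5, core = 2.5))
    fadg <- list(alpha2 = c(edge = 0.25, core = 0.25),
                 tau1 = c(edge = 0.3, core = 0.3),
                 tau2 = c(edge = 2.0, core = 2.0))
    cfg$conditions <- list(
      list(label = "d0", cell_line = "sim", collagen_mg_ml = 1, day = 0,
           scene_kind = "intact", radius_px = 28L, n_blobs = 0L,
           nadh_gradient = day0, fad_gradient = fadg),
      list(label = "d3", cell_line = "sim", collagen_mg_ml = 1, day = 3,
           scene_kind = "intact", radius_px = 28L, n_blobs = 0L,
           nadh_gradient = day3, fad_gradient = fadg))
  }
  if (is.null(cfg$comparisons))
    cfg$comparisons <- list(c(cfg$conditions[[1]]$label,
                              cfg$conditions[[length(cfg$conditions)]]$label))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$phantom
  if (is.null(p$n_replicates) || p$n_replicates < 1L)
    abort("n_replicates must be >= 1", "spheroflim_invalid_argument")
  if (p$photons_per_pixel < 0)
    abort("photons_per_pixel must be non-negative", "spheroflim_invalid_argument")
  if (cfg$image$n_bins %% cfg$fit$t_out != 0L)
    abort("t_out must divide n_bins", "spheroflim_invalid_argument")
  if (!length(cfg$conditions))
    abort("at least one condition is required", "spheroflim_invalid_argument")
  labs <- vapply(cfg$conditions, `[[`, "", "label")
  if (anyDuplicated(labs))
    abort("condition labels must be unique", "spheroflim_invalid_argument")
  for (cmp in cfg$comparisons)
    if (!all(cmp %in% labs))
      abort("comparison refers to an unknown condition label",
            "spheroflim_invalid_argument")
  invisible(cfg)
}

#' Write the default configuration to a YAML file
#'
#' @param path output YAML path.
#' @param config configuration to write (default: [pipeline_config()]).
#' @return `path`, invisibly.
#' @export
config_init <- function(path, config = pipeline_config()) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path written by [config_init()] (possibly edited).
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # restore c(edge, core) numeric vectors possibly serialized as lists
  fix_grad <- function(g) lapply(g, function(v) unlist(v))
  raw$conditions <- lapply(raw$conditions, function(cd) {
    cd$nadh_gradient <- fix_grad(cd$nadh_gradient)
    cd$fad_gradient <- fix_grad(cd$fad_gradient)
    cd
  })
  do.call(pipeline_config, raw)
}

# internal: IRF per channel from config (synthetic Gaussian or measured CSV)
config_irf <- function(cfg, channel) {
  csv <- if (channel == "NADH") cfg$irf$nadh_csv else cfg$irf$fad_csv
  if (!is.null(csv)) return(read_irf(csv))
  fwhm <- if (channel == "NADH") cfg$irf$nadh_fwhm_ps else cfg$irf$fad_fwhm_ps
  make_irf(fwhm, n_bins = cfg$image$n_bins,
           bin_width_ps = cfg$image$period_ns * 1000 / cfg$image$n_bins,
           center_bin = cfg$irf$center_bin)
}

# internal: process one replicate of one condition end to end
run_replicate <- function(cfg, cond, irf_n, irf_f, rep_seed) {
  scene <- make_phantom(cond$scene_kind, size = cfg$image$size,
                        pixel_size_um = cfg$image$pixel_size_um,
                        radius_px = cond$radius_px, n_blobs = cond$n_blobs,
                        gradient = cond$nadh_gradient,
                        core_depth_um = cfg$spatial$core_from_um,
                        seed = rep_seed)
  scene_f <- scene_with_gradient(scene, cond$fad_gradient,
                                 core_depth_um = cfg$spatial$core_from_um)
  dk_n <- simulate_decay_image(scene, irf_n, cfg$phantom$photons_per_pixel,
                               period_ns = cfg$image$period_ns,
                               channel = "NADH",
                               dark_rate = cfg$phantom$dark_rate,
                               seed = derive_seed(rep_seed, 1))
  dk_f <- simulate_decay_image(scene_f, irf_f, cfg$phantom$photons_per_pixel,
                               period_ns = cfg$image$period_ns,
                               channel = "FAD",
                               dark_rate = cfg$phantom$dark_rate,
                               seed = derive_seed(rep_seed, 2))
  intens <- intensity_from_decay(dk_n)
  mask <- if (cond$scene_kind == "scattered") {
    segment_migratory(intens,
                      tophat_radius_px = cfg$segmentation$tophat_radius_px,
                      sensitivity = cfg$segmentation$sensitivity)
  } else {
    segment_intact(intens,
                   dilate_radius_px = cfg$segmentation$dilate_radius_px)
  }
  fcfg <- fit_config(n_restarts = cfg$fit$n_restarts,
                     model_grid = cfg$fit$model_grid)
  fit_n <- fit_image(spatial_temporal_bin(dk_n, mask, cfg$fit$window,
                                          cfg$fit$t_out),
                     irf_n, fcfg, seed = derive_seed(rep_seed, 3),
                     stride = cfg$fit$stride)
  fit_f <- fit_image(spatial_temporal_bin(dk_f, mask, cfg$fit$window,
                                          cfg$fit$t_out),
                     irf_f, fcfg, seed = derive_seed(rep_seed, 4),
                     stride = cfg$fit$stride)
  flirr <- compute_flirr(fit_n, fit_f, eps = cfg$flirr$eps)

  if (cond$scene_kind == "intact") {
    dmap <- distance_from_edge(mask)
    center <- find_center(mask)
  } else {
    center <- if (cond$scene_kind == "scattered") scene$center else
      find_center(mask)
    dmap <- distance_from_center(mask, center)
  }
  profile <- bin_flirr_by_distance(flirr, dmap,
                                   edge_bin_um = cfg$spatial$edge_bin_um,
                                   core_from_um = cfg$spatial$core_from_um,
                                   center_bin_um = cfg$spatial$center_bin_um)
  migr <- migration_summary(distance_from_center(mask, center))
  fv <- flirr$values[flirr$mask]
  pos <- fv > 0                       # the log-scale KDE needs positive values
  list(scene = scene, mask = mask, flirr = flirr, profile = profile,
       migration = migr, area = spheroid_area(mask),
       flirr_values = fv[pos],
       n_dropped = flirr$n_dropped + sum(!pos),
       n_no_signal = fit_n$n_no_signal)
}

#' Run the full simulate-segment-fit-FLIRR-spatial pipeline
#'
#' Executes every configured condition and replicate, pools FLIRR values
#' across the replicates of each condition, estimates the condition PDFs on
#' the fixed grid, computes the configured pairwise overlap indices and
#' median t-tests, and writes tidy outputs under `output_dir`:
#' `profile_<label>_rep<k>.csv` (distance-binned FLIRR),
#' `morphology.csv` (areas and migration percentiles),
#' `pdf_<label>.csv` (grid, density), `comparisons.json`, and
#' `manifest.json` (config snapshot, package version, seed, per-stage
#' warnings and dropped-pixel counts).
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for outputs (created if missing).
#' @return Invisibly, a list with `pdfs`, `comparisons`, `replicates`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir) {
  validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  irf_n <- config_irf(config, "NADH")
  irf_f <- config_irf(config, "FAD")
  grid <- seq(config$flirr$grid_from, config$flirr$grid_to,
              by = config$flirr$grid_by)

  reps <- list()
  pooled <- list()
  medians <- list()
  morph_rows <- list()
  stage_log <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    cond_flirr <- numeric(0)
    cond_medians <- numeric(0)
    for (r in seq_len(config$phantom$n_replicates)) {
      rep_seed <- derive_seed(config$seed, ci * 1000 + r)
      res <- tryCatch(
        run_replicate(config, cond, irf_n, irf_f, rep_seed),
        error = function(e) {
          abort(sprintf("stage failure in condition \"%s\" replicate %d: %s",
                        cond$label, r, conditionMessage(e)),
                "spheroflim_stage_failure")
        })
      reps[[sprintf("%s_rep%d", cond$label, r)]] <- res
      cond_flirr <- c(cond_flirr, res$flirr_values)
      cond_medians <- c(cond_medians, median(res$flirr_values))
      write.csv(cbind(condition = cond$label, replicate = r,
                      res$profile$table),
                file.path(output_dir,
                          sprintf("profile_%s_rep%d.csv", cond$label, r)),
                row.names = FALSE)
      morph_rows[[length(morph_rows) + 1L]] <- data.frame(
        condition = cond$label, replicate = r, area_pixels = res$area,
        t(res$migration$percentiles))
      stage_log[[sprintf("%s_rep%d", cond$label, r)]] <-
        list(n_flirr_dropped = res$n_dropped,
             n_no_signal = res$n_no_signal)
    }
    pooled[[cond$label]] <- cond_flirr
    medians[[cond$label]] <- cond_medians
  }

  write.csv(do.call(rbind, morph_rows),
            file.path(output_dir, "morphology.csv"), row.names = FALSE)

  pdfs <- lapply(pooled, estimate_pdf, grid = grid)
  for (lab in names(pdfs))
    write.csv(data.frame(flirr = pdfs[[lab]]$grid,
                         density = pdfs[[lab]]$density),
              file.path(output_dir, sprintf("pdf_%s.csv", lab)),
              row.names = FALSE)

  comparisons <- lapply(config$comparisons, function(pair) {
    cm <- compare_medians(medians[[pair[1]]], medians[[pair[2]]])
    list(a = pair[1], b = pair[2],
         overlap_index = overlap_index(pdfs[[pair[1]]], pdfs[[pair[2]]]),
         t_statistic = cm$t_statistic, p_value = cm$p_value,
         significant = cm$significant)
  })
  jsonlite::write_json(comparisons,
                       file.path(output_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(package = "spheroflim",
                   version = as.character(packageVersion("spheroflim")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = stage_log,
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pdfs = pdfs, comparisons = comparisons, replicates = reps,
                 manifest = manifest))
}
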