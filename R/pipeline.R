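# End-to-end workflow driver: simulate -> preprocess -> calibrate ->
# quantify -> render, writing every artefact plus a machine-readable report
# and a hashed manifest into a fresh run directory.

#' Build a pipeline run configuration
#'
#' A plain named list with one section per stage; [validate_run_config()]
#' checks every stage's parameters against its preconditions before any work
#' starts. Configurations can also be read from YAML via [read_run_config()].
#'
#' The segmentation `threshold` is expressed in calibrated gray values and
#' has no universal default in principle (it must be chosen once per study
#' and applied identically to every specimen); the default here is matched
#' to the default simulated gray levels.
#'
#' @param seed Integer master seed.
#' @param simulate List: `shape` `(nz, ny, nx)`, `target_vf`,
#'   `feature_scale_um`, `noise_sigma` (raw-scale SD), `voxel_size_um`,
#'   `air_margin` (x/y border of air around the wax block, voxels),
#'   `voi_margin` (border excluded from the quantified VOI, voxels).
#' @param calibrate List: `raw_gray_air`, `raw_gray_wax`, `raw_gray_tissue`
#'   (float means of the simulated raw scans), `method`.
#' @param preprocess List: `median_radius`, `unsharp_sigma`, `unsharp_weight`,
#'   `window` (`c(lo, hi)`).
#' @param quantify List: `threshold` (absolute calibrated gray),
#'   `bin_width_um`.
#' @param render List: `mip_axes` (subset of x/y/z).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       simulate = list(shape = c(40L, 96L, 96L), target_vf = 0.33,
                                       feature_scale_um = 34, noise_sigma = 1.5,
                                       voxel_size_um = 8.48, air_margin = 16L,
                                       voi_margin = 32L),
                       calibrate = list(raw_gray_air = 10, raw_gray_wax = 55,
                                        raw_gray_tissue = 72,
                                        method = "histogram_peaks"),
                       preprocess = list(median_radius = 1L, unsharp_sigma = 2,
                                         unsharp_weight = 0.6,
                                         window = c(-50, 100)),
                       quantify = list(threshold = 23000, bin_width_um = 8.48),
                       render = list(mip_axes = c("z", "y"))) {
  cfg <- structure(list(seed = as.integer(seed), simulate = simulate,
                        calibrate = calibrate, preprocess = preprocess,
                        quantify = quantify, render = render),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param path YAML file with the same sections.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- unclass(run_config())
  for (sec in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[sec]])) cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
    else cfg[[sec]] <- raw[[sec]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg <- structure(cfg, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config` to check.
#' @export
validate_run_config <- function(config) {
  fail <- function(stage, field, msg)
    stop(sprintf("invalid config: stage '%s', field '%s': %s", stage, field, msg),
         call. = FALSE)
  s <- config$simulate
  if (length(s$shape) != 3L || any(s$shape < 8)) fail("simulate", "shape", "need a (nz,ny,nx) triple, all >= 8")
  if (!(s$target_vf > 0 && s$target_vf < 1)) fail("simulate", "target_vf", "must be in (0, 1)")
  if (s$feature_scale_um <= 0) fail("simulate", "feature_scale_um", "must be > 0")
  if (s$noise_sigma < 0) fail("simulate", "noise_sigma", "must be >= 0")
  if (s$voi_margin <= s$air_margin) fail("simulate", "voi_margin", "must exceed air_margin")
  cal <- config$calibrate
  if (!(cal$raw_gray_air < cal$raw_gray_wax && cal$raw_gray_wax < cal$raw_gray_tissue))
    fail("calibrate", "raw_gray_*", "need air < wax < tissue")
  p <- config$preprocess
  if (p$median_radius < 1) fail("preprocess", "median_radius", "must be >= 1")
  if (p$unsharp_sigma <= 0) fail("preprocess", "unsharp_sigma", "must be > 0")
  if (p$unsharp_weight <= 0 || p$unsharp_weight >= 1) fail("preprocess", "unsharp_weight", "must be in (0, 1)")
  if (length(p$window) != 2L || p$window[1] >= p$window[2])
    fail("preprocess", "window", "need lo < hi")
  q <- config$quantify
  if (is.null(q$threshold)) fail("quantify", "threshold", "an absolute threshold is required")
  if (q$bin_width_um <= 0) fail("quantify", "bin_width_um", "must be > 0")
  ax <- config$render$mip_axes
  if (length(ax) && !all(ax %in% c("x", "y", "z"))) fail("render", "mip_axes", "axes must be x, y or z")
  invisible(config)
}

# Simulated FFPE block on the raw float scale (air surround, wax block,
# foam-like tissue inside the VOI), with ground truth by construction.
.simulate_block <- function(s, cal, seed) {
  bp <- make_block_phantom(
    phantom_spec(shape = s$shape, voxel_size_um = s$voxel_size_um,
                 gray_air = cal$raw_gray_air, gray_wax = cal$raw_gray_wax,
                 gray_tissue = cal$raw_gray_tissue,
                 noise_sigma = s$noise_sigma, seed = seed),
    target_vf = s$target_vf, feature_scale_um = s$feature_scale_um,
    air_margin = s$air_margin, voi_margin = s$voi_margin,
    calibration_state = "raw")
  list(volume = bp$volume, tissue_mask = bp$ground_truth$tissue_mask,
       voi = bp$ground_truth$voi,
       true_volume_fraction = bp$ground_truth$true_volume_fraction)
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulates a raw-scale FFPE-like sample (air surround, wax block,
#' foam-architecture tissue) and a wax calibration phantom, runs the
#' preprocessing chain on both, calibrates the sample against the phantom
#' (air to 0), segments and quantifies the tissue in the VOI, renders MIPs,
#' and writes every artefact plus `report.json` and an MD5 `manifest.csv`
#' into `out_dir`. Deterministic under `config$seed`; no stage mutates its
#' inputs.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if missing).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  logit <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  stage <- function(name, expr) {
    logit("[%s] start", name)
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    logit("[%s] done", name)
    r
  }
  s <- config$simulate; cal <- config$calibrate; p <- config$preprocess
  q <- config$quantify

  sim <- stage("simulate", {
    blk <- .simulate_block(s, cal, config$seed)
    ph <- make_calibration_phantom(phantom_spec(
      shape = s$shape, voxel_size_um = s$voxel_size_um,
      gray_air = cal$raw_gray_air, gray_wax = cal$raw_gray_wax,
      gray_tissue = cal$raw_gray_tissue, noise_sigma = s$noise_sigma,
      seed = config$seed + 1L))
    ph$meta$calibration_state <- "raw"
    write_volume(blk$volume, file.path(out_dir, "sample_raw.raw"))
    write_volume(ph, file.path(out_dir, "phantom_raw.raw"))
    list(block = blk, phantom = ph)
  })

  pre <- stage("preprocess", {
    w <- window_spec(p$window[1], p$window[2])
    sp <- preprocess_volume(sim$block$volume, p$median_radius, p$unsharp_sigma,
                            p$unsharp_weight, w)
    pp <- preprocess_volume(sim$phantom, p$median_radius, p$unsharp_sigma,
                            p$unsharp_weight, w)
    write_volume(sp, file.path(out_dir, "sample16.tif"))
    write_volume(pp, file.path(out_dir, "phantom16.tif"))
    list(sample = sp, phantom = pp)
  })

  calres <- stage("calibrate", {
    res <- calibrate(pre$sample, pre$phantom, method = cal$method)
    jsonlite::write_json(list(
      phantom_levels = unclass(res$phantom_levels),
      sample_levels = unclass(res$sample_levels),
      contrast_factor_phantom = res$contrast_factor_phantom,
      contrast_factor_sample = res$contrast_factor_sample,
      calibration_factor = res$calibration_factor,
      air_offset = res$air_offset),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  calvol <- stage("apply_calibration", {
    v <- apply_calibration(pre$sample, calres)
    write_volume(v, file.path(out_dir, "sample_cal.tif"))
    v
  })

  morpho <- stage("quantify", {
    bin <- segment_tissue(calvol, q$threshold, sim$block$voi)
    rep <- morphometry_report(bin, q$bin_width_um)
    utils::write.csv(rep$thickness_histogram,
                     file.path(out_dir, "thickness_histogram.csv"),
                     row.names = FALSE)
    rep
  })

  stage("render", {
    for (ax in config$render$mip_axes) {
      img <- mip(calvol, ax)
      mx <- max(img)
      write_image(if (mx > 0) img / mx else img,
                  file.path(out_dir, sprintf("mip_%s.png", ax)))
    }
    NULL
  })

  report <- list(
    seed = config$seed,
    calibration = list(calibration_factor = calres$calibration_factor,
                       air_offset = calres$air_offset,
                       contrast_factor_phantom = calres$contrast_factor_phantom,
                       contrast_factor_sample = calres$contrast_factor_sample),
    morphometry = list(mean_thickness_um = morpho$mean_thickness_um,
                       sd_thickness_um = morpho$sd_thickness_um,
                       volume_fraction = morpho$volume_fraction,
                       n_voxels = morpho$n_voxels),
    ground_truth = list(volume_fraction = sim$block$true_volume_fraction))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(out_dir), c("manifest.csv", "run.log"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  logit("[report] written")
  invisible(report)
}
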