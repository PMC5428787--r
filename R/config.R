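#' Default run configuration
#'
#' Nested list with sections `camera`, `detection`, `threshold`, `linking`,
#' `quantify`, `sholl`, `simulate`, plus a master `seed`. The simulate section
#' defaults encode the growth-cone acquisition protocol: 60 s baseline
#' followed by 120 s of post-treatment imaging at 200 ms exposure, baseline
#' 15 events/min doubling to 30 events/min from ~20 s after the stimulus and
#' relaxing with a 30 s time constant, flashes of ~400 ms carrying ~500
#' expected photons.
#'
#' @return A named list of class `smti_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    camera = list(
      pixel_size_nm = 118, exposure_s = 0.2, em_gain = 200,
      adc_per_photon = 13.4, offset_adc = 100, read_noise_adc = 10
    ),
    detection = list(
      smoothing_sigma_px = 1.1, detect_threshold_adc = 20,
      window_px = 7L, max_iterations = 200L, convergence_tol = 1e-6
    ),
    threshold = list(
      threshold_photons = 30, stage = "event"
    ),
    linking = list(
      search_radius_nm = 236, max_gap_frames = 1L
    ),
    quantify = list(
      window_s = 10, step_s = 1, density_bin_nm = 118,
      density_kernel_sigma_nm = 236, crop_to_mask = TRUE
    ),
    sholl = list(
      n_arcs = 5L
    ),
    simulate = list(
      grid_shape = c(96L, 96L), n_frames = 900L,
      baseline_rate_per_min = 15, stimulated_rate_per_min = 30,
      stimulus_time_s = 60, onset_delay_s = 20, decay_time_s = 30,
      mean_flash_duration_s = 0.4, photon_rate_per_s = 1250,
      maturation_delay_s = 0, psf_sigma_nm = 130,
      background_photons_per_px = 0.5
    )
  ), class = "smti_config")
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; values are validated against the documented
#' schema with field paths in error messages. Sections missing from the file
#' fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No config file at '%s'.", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      abort(sprintf("Unknown config section '%s'.", section))
    }
    if (section == "seed") {
      cfg$seed <- user$seed
      next
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        abort(sprintf("Unknown config field '%s.%s'.", section, key))
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config An `smti_config` list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(validate_config(config))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' @param config Config list as from [default_config()].
#' @return The validated config (invisibly usable in pipelines).
#' @export
validate_config <- function(config) {
  cfg <- config
  chk <- function(val, path, lower = -Inf, test = NULL) {
    if (!is.numeric(val) || any(!is.finite(val)) || any(val < lower)) {
      abort(sprintf("Config field '%s' is invalid (got %s).",
                    path, paste(format(val), collapse = ", ")))
    }
  }
  chk(cfg$seed, "seed", lower = 0)
  with(cfg$camera, {
    chk(pixel_size_nm, "camera.pixel_size_nm", lower = 1e-9)
    chk(exposure_s, "camera.exposure_s", lower = 1e-12)
    chk(em_gain, "camera.em_gain", lower = 1)
    chk(adc_per_photon, "camera.adc_per_photon", lower = 1e-12)
    chk(offset_adc, "camera.offset_adc", lower = 0)
    chk(read_noise_adc, "camera.read_noise_adc", lower = 0)
  })
  with(cfg$detection, {
    chk(smoothing_sigma_px, "detection.smoothing_sigma_px", lower = 0.1)
    chk(detect_threshold_adc, "detection.detect_threshold_adc", lower = 1e-12)
    chk(window_px, "detection.window_px", lower = 5)
    if (cfg$detection$window_px %% 2 == 0) {
      abort("Config field 'detection.window_px' must be odd.")
    }
    chk(max_iterations, "detection.max_iterations", lower = 1)
    chk(convergence_tol, "detection.convergence_tol", lower = 0)
  })
  chk(cfg$threshold$threshold_photons, "threshold.threshold_photons", lower = 0)
  if (!cfg$threshold$stage %in% c("localization", "event")) {
    abort("Config field 'threshold.stage' must be 'localization' or 'event'.")
  }
  chk(cfg$linking$search_radius_nm, "linking.search_radius_nm", lower = 0)
  chk(cfg$linking$max_gap_frames, "linking.max_gap_frames", lower = 0)
  with(cfg$quantify, {
    chk(window_s, "quantify.window_s", lower = 1e-9)
    chk(step_s, "quantify.step_s", lower = 1e-9)
    chk(density_bin_nm, "quantify.density_bin_nm", lower = 1e-9)
    chk(density_kernel_sigma_nm, "quantify.density_kernel_sigma_nm", lower = 0)
  })
  if (!is.logical(cfg$quantify$crop_to_mask) ||
      length(cfg$quantify$crop_to_mask) != 1) {
    abort("Config field 'quantify.crop_to_mask' must be TRUE or FALSE.")
  }
  chk(cfg$sholl$n_arcs, "sholl.n_arcs", lower = 1)
  with(cfg$simulate, {
    chk(grid_shape, "simulate.grid_shape", lower = 32)
    chk(n_frames, "simulate.n_frames", lower = 1)
    chk(baseline_rate_per_min, "simulate.baseline_rate_per_min", lower = 0)
    chk(stimulated_rate_per_min, "simulate.stimulated_rate_per_min", lower = 0)
    chk(stimulus_time_s, "simulate.stimulus_time_s", lower = 0)
    chk(onset_delay_s, "simulate.onset_delay_s", lower = 0)
    chk(mean_flash_duration_s, "simulate.mean_flash_duration_s", lower = 0)
    chk(photon_rate_per_s, "simulate.photon_rate_per_s", lower = 0)
    chk(maturation_delay_s, "simulate.maturation_delay_s", lower = 0)
    chk(psf_sigma_nm, "simulate.psf_sigma_nm", lower = 1e-9)
    chk(background_photons_per_px, "simulate.background_photons_per_px",
        lower = 0)
  })
  if (is.finite(cfg$simulate$decay_time_s) && cfg$simulate$decay_time_s <= 0) {
    abort("Config field 'simulate.decay_time_s' must be positive (or Inf).")
  }
  structure(cfg, class = "smti_config")
}

#' Build a camera model from a config
#' @param config An `smti_config` list.
#' @export
config_camera <- function(config) {
  do.call(camera_model, config$camera)
}
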