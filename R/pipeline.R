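#' Match detected events against simulator ground truth
#'
#' One-to-one greedy matching by normalized spatiotemporal distance: a
#' detected event may match a true event if within `match_radius_nm` in
#' space and `match_time_s` in start time; candidate pairs are accepted in
#' order of increasing combined distance. The quality gate behind all
#' end-to-end validation.
#'
#' @param events Detected event tibble (`x_nm`, `y_nm`, `t_start_s`).
#' @param truth Ground-truth tibble from [sample_events()] (non-empty).
#' @param match_radius_nm Spatial gate, nm.
#' @param match_time_s Temporal gate on start times, seconds.
#' @return An object of class `smti_validation`: list with `recall`,
#'   `precision` (`NaN` when nothing was detected), `rmse_nm` (position RMSE
#'   over matched pairs), `rate_error` (relative count error), `n_true`,
#'   `n_detected`, `n_matched`.
#' @export
validate_against_truth <- function(events, truth, match_radius_nm = 250,
                                   match_time_s = 0.6) {
  if (nrow(truth) == 0) abort("`truth` must be non-empty.")
  check_number(match_radius_nm, "match_radius_nm", lower = 1e-12)
  check_number(match_time_s, "match_time_s", lower = 1e-12)
  n_t <- nrow(truth); n_d <- nrow(events)
  if (n_d == 0) {
    return(structure(
      list(recall = 0, precision = NaN, rmse_nm = NaN,
           rate_error = -1, n_true = n_t, n_detected = 0L, n_matched = 0L),
      class = "smti_validation"
    ))
  }
  dx <- outer(events$x_nm, truth$true_x_nm, "-")
  dy <- outer(events$y_nm, truth$true_y_nm, "-")
  dt <- abs(outer(events$t_start_s, truth$true_t_s, "-"))
  ds <- sqrt(dx^2 + dy^2)
  ok <- ds <= match_radius_nm & dt <= match_time_s
  score <- sqrt((ds / match_radius_nm)^2 + (dt / match_time_s)^2)
  pairs <- which(ok, arr.ind = TRUE)
  used_d <- rep(FALSE, n_d); used_t <- rep(FALSE, n_t)
  matched_ds2 <- c()
  if (nrow(pairs) > 0) {
    ord <- order(score[pairs])
    for (j in ord) {
      di <- pairs[j, 1]; ti <- pairs[j, 2]
      if (used_d[di] || used_t[ti]) next
      used_d[di] <- TRUE; used_t[ti] <- TRUE
      matched_ds2 <- c(matched_ds2, ds[di, ti]^2)
    }
  }
  n_m <- sum(used_d)
  structure(
    list(
      recall = n_m / n_t,
      precision = n_m / n_d,
      rmse_nm = if (n_m > 0) sqrt(mean(matched_ds2)) else NaN,
      rate_error = (n_d - n_t) / n_t,
      n_true = n_t, n_detected = n_d, n_matched = n_m
    ),
    class = "smti_validation"
  )
}

#' @export
print.smti_validation <- function(x, ...) {
  cat(sprintf(
    "<smti_validation> recall %.3f, precision %.3f, RMSE %.1f nm (%d/%d/%d true/detected/matched)\n",
    x$recall, x$precision, x$rmse_nm, x$n_true, x$n_detected, x$n_matched
  ))
  invisible(x)
}

#' Run the full SMTI pipeline
#'
#' Executes the enabled stages in order — simulate, localize, events,
#' quantify, sholl, validate — writing every intermediate artifact to
#' `out_dir` plus a run manifest (config hash, master and per-stage seeds,
#' package version, per-stage counts, and an md5 content hash of every
#' output file). Identical config and seed reproduce byte-identical tables.
#'
#' @param config An `smti_config` (see [default_config()], [read_config()]).
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "localize", "events",
                                    "quantify", "sholl", "validate")) {
  cfg <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cam <- config_camera(cfg)
  seed <- cfg$seed
  counts <- list()
  outputs <- character()
  add_output <- function(path) outputs <<- c(outputs, path)

  path_of <- function(name) file.path(out_dir, name)
  write_config(cfg, path_of("config_used.yaml"))
  add_output(path_of("config_used.yaml"))

  sim <- NULL; movie <- NULL; geometry <- NULL; truth <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_movie(cfg, seed = seed)
    movie <- sim$movie; geometry <- sim$geometry; truth <- sim$truth
    write_movie(movie, path_of("movie.tif"))
    write_mask(geometry$mask, path_of("mask.tif"))
    write_ground_truth(truth, path_of("ground_truth.csv"))
    add_output(path_of("movie.tif")); add_output(path_of("mask.tif"))
    add_output(path_of("ground_truth.csv"))
    counts$simulated_events <- nrow(truth)
    inform(sprintf("simulate: %d events over %d frames", nrow(truth),
                   n_frames(movie)))
  }

  locs <- NULL
  if ("localize" %in% stages) {
    if (is.null(movie)) abort("localize stage needs a simulated movie.")
    params <- do.call(detection_params, cfg$detection)
    locs <- localize_movie(movie, params)
    write_localizations(locs, path_of("localizations.csv"))
    add_output(path_of("localizations.csv"))
    counts$localizations <- nrow(locs)
  }

  events <- NULL
  if ("events" %in% stages) {
    if (is.null(locs)) abort("events stage needs localizations.")
    thr <- cfg$threshold$threshold_photons
    if (cfg$threshold$stage == "localization") {
      kept <- apply_photon_threshold(locs, thr)
      events <- link_localizations(
        kept, search_radius_nm = cfg$linking$search_radius_nm,
        max_gap_frames = cfg$linking$max_gap_frames, camera = cam
      )
    } else {
      events <- link_localizations(
        locs, search_radius_nm = cfg$linking$search_radius_nm,
        max_gap_frames = cfg$linking$max_gap_frames, camera = cam
      )
      events <- events[events$total_photons >= thr, , drop = FALSE]
    }
    if (isTRUE(cfg$quantify$crop_to_mask) && !is.null(geometry)) {
      # restrict analysis to the cell, as the tight growth-cone crop does;
      # 1 px tolerance absorbs localization error at thin filopodia
      events <- events[events_in_mask(events, geometry, dilate_px = 1), ,
                       drop = FALSE]
    }
    events$event_id <- seq_len(nrow(events))
    write_events(events, path_of("events.csv"))
    add_output(path_of("events.csv"))
    counts$events <- nrow(events)
    inform(sprintf("events: %d events after %s-level threshold of %g photons",
                   nrow(events), cfg$threshold$stage, thr))
  }

  if ("quantify" %in% stages) {
    if (is.null(events) || is.null(geometry)) {
      abort("quantify stage needs events and a geometry.")
    }
    duration <- n_frames(movie) * cam$exposure_s
    stim <- cfg$simulate$stimulus_time_s
    course <- rate_time_course(
      events, window_s = cfg$quantify$window_s, step_s = cfg$quantify$step_s,
      t_span = c(0, duration), stimulus_time_s = stim
    )
    readr::write_csv(tibble::as_tibble(course), path_of("rate_course.csv"))
    add_output(path_of("rate_course.csv"))
    dmap <- density_map(
      events, geometry, bin_size_nm = cfg$quantify$density_bin_nm,
      kernel_sigma_nm = cfg$quantify$density_kernel_sigma_nm,
      duration_s = duration
    )
    utils::write.csv(dmap$grid, path_of("density_map.csv"),
                     row.names = FALSE)
    add_output(path_of("density_map.csv"))
    summary <- list(
      n_events = nrow(events),
      duration_s = duration,
      mean_rate_per_s = nrow(events) / duration,
      area_normalized_rate_per_s_um2 =
        area_normalized_rate(events, geometry, duration)
    )
    if (!is.null(stim) && stim > 0 && stim < duration) {
      resp_end <- min(stim + 60, duration)
      pp <- pre_post_comparison(course, c(0, stim), c(stim, resp_end))
      summary$baseline_rate_per_s <- pp$baseline_rate_per_s
      summary$response_rate_per_s <- pp$response_rate_per_s
      summary$fold_change <- pp$fold_change
    }
    jsonlite::write_json(summary, path_of("summary.json"),
                         auto_unbox = TRUE, digits = NA)
    add_output(path_of("summary.json"))
    counts$rate_grid_points <- nrow(course)
  }

  if ("sholl" %in% stages) {
    if (is.null(events) || is.null(geometry)) {
      abort("sholl stage needs events and a geometry.")
    }
    radii <- sholl_radii(geometry, n_arcs = cfg$sholl$n_arcs)
    sh <- assign_events_to_arcs(events, geometry, radii)
    readr::write_csv(tibble::as_tibble(sh), path_of("sholl.csv"))
    add_output(path_of("sholl.csv"))
    counts$sholl_events <- attr(sh, "total_events")
  }

  validation <- NULL
  if ("validate" %in% stages && !is.null(truth) && nrow(truth) > 0 &&
      !is.null(events)) {
    validation <- validate_against_truth(events, truth)
    jsonlite::write_json(unclass(validation), path_of("validation.json"),
                         auto_unbox = TRUE, digits = NA)
    add_output(path_of("validation.json"))
    counts$matched_events <- validation$n_matched
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("smti")),
    master_seed = seed,
    stage_seeds = list(
      simulate = derive_seed(seed, "simulate"),
      events = derive_seed(seed, "events"),
      render = derive_seed(seed, "render")
    ),
    config_md5 = unname(tools::md5sum(path_of("config_used.yaml"))),
    stages = stages,
    counts = counts,
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(p) list(md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
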