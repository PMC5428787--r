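#' Flash kinetics of the translation reporter
#'
#' A newly synthesized fast-folding reporter emits a single short burst
#' (~400 ms) before irreversible photobleaching. Burst durations are drawn
#' from an exponential distribution (single-step photobleaching) truncated at
#' five times the mean; the photon budget of a flash is
#' `photon_rate_per_s * duration`, so a full-length flash carries ~500
#' detected photons at the defaults.
#'
#' @param mean_flash_duration_s Mean burst duration, seconds.
#' @param photon_rate_per_s Expected detected photons per second while
#'   emitting.
#' @param maturation_delay_s Fixed delay between synthesis and the start of
#'   emission (chromophore maturation), seconds.
#' @return An object of class `smti_flash_kinetics`.
#' @export
flash_kinetics <- function(mean_flash_duration_s = 0.4,
                           photon_rate_per_s = 1250,
                           maturation_delay_s = 0) {
  check_number(mean_flash_duration_s, "mean_flash_duration_s", lower = 0)
  check_number(photon_rate_per_s, "photon_rate_per_s", lower = 0)
  check_number(maturation_delay_s, "maturation_delay_s", lower = 0)
  structure(
    list(
      mean_flash_duration_s = mean_flash_duration_s,
      photon_rate_per_s = photon_rate_per_s,
      maturation_delay_s = maturation_delay_s
    ),
    class = "smti_flash_kinetics"
  )
}

#' Piecewise translation-rate profile with a stimulated phase
#'
#' Describes the event rate of the inhomogeneous Poisson process: a constant
#' baseline, then — from `onset_delay_s` after the stimulus — a step to the
#' stimulated rate that optionally relaxes back toward baseline with time
#' constant `decay_time_s` (set `Inf` for a pure step).
#'
#' @param baseline_rate_per_min Events per minute before the response onset.
#' @param stimulated_rate_per_min Peak events per minute after onset.
#' @param stimulus_time_s Time the cue is added, seconds (NULL for none).
#' @param onset_delay_s Latency between cue addition and the rate increase.
#' @param decay_time_s Exponential relaxation time constant (seconds, or
#'   `Inf` for a sustained step).
#' @return An object of class `smti_rate_profile`.
#' @export
rate_profile <- function(baseline_rate_per_min = 15,
                         stimulated_rate_per_min = 30,
                         stimulus_time_s = 60, onset_delay_s = 20,
                         decay_time_s = 30) {
  check_number(baseline_rate_per_min, "baseline_rate_per_min", lower = 0)
  check_number(stimulated_rate_per_min, "stimulated_rate_per_min", lower = 0)
  if (!is.null(stimulus_time_s)) {
    check_number(stimulus_time_s, "stimulus_time_s", lower = 0)
  }
  check_number(onset_delay_s, "onset_delay_s", lower = 0)
  if (!(is.numeric(decay_time_s) && length(decay_time_s) == 1 &&
        (is.infinite(decay_time_s) || decay_time_s > 0))) {
    abort("`decay_time_s` must be positive or Inf.")
  }
  structure(
    list(
      baseline_rate_per_min = baseline_rate_per_min,
      stimulated_rate_per_min = stimulated_rate_per_min,
      stimulus_time_s = stimulus_time_s, onset_delay_s = onset_delay_s,
      decay_time_s = decay_time_s
    ),
    class = "smti_rate_profile"
  )
}

#' Instantaneous event rate of a profile
#'
#' @param profile A [rate_profile()].
#' @param t_s Times (seconds), vectorized.
#' @return Rate in events per minute at each time.
#' @export
profile_rate_per_min <- function(profile, t_s) {
  stopifnot(inherits(profile, "smti_rate_profile"))
  base <- profile$baseline_rate_per_min
  if (is.null(profile$stimulus_time_s)) return(rep(base, length(t_s)))
  t_on <- profile$stimulus_time_s + profile$onset_delay_s
  r <- rep(base, length(t_s))
  post <- t_s >= t_on
  if (any(post)) {
    excess <- profile$stimulated_rate_per_min - base
    if (is.infinite(profile$decay_time_s)) {
      r[post] <- base + excess
    } else {
      r[post] <- base + excess * exp(-(t_s[post] - t_on) / profile$decay_time_s)
    }
  }
  r
}

#' Synthetic growth-cone mask
#'
#' Builds a fan-shaped binary mask reminiscent of an axonal growth cone: a
#' lamellipodial fan spreading from a proximal base point, with a smoothly
#' irregular boundary and a handful of filopodia-like radial protrusions.
#' The shape is star-convex about the base, hence always connected, and is
#' deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param grid_shape `c(rows, cols)`, at least 32 x 32.
#' @param pixel_size_nm Pixel size of the raster, nm.
#' @param scale Relative size of the fan (1 fills ~40% of the shorter grid
#'   side with its radius).
#' @return A [cell_geometry()] of kind `"growth_cone"` whose base point sits
#'   on the proximal mask boundary.
#' @export
make_growth_cone_mask <- function(seed, grid_shape = c(96L, 96L),
                                  pixel_size_nm = 118, scale = 1) {
  if (any(grid_shape < 32)) abort("`grid_shape` must be at least 32 x 32.")
  check_number(scale, "scale", lower = 0.1)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  with_seed(derive_seed(seed, "mask"), {
    # base point near the bottom-center of the grid, fan opening upward
    bx <- nc / 2 + runif(1, -0.05, 0.05) * nc
    by <- 0.82 * nr
    r0 <- 0.42 * min(nr, nc) * scale
    fan_half <- runif(1, 1.0, 1.3)      # half-opening angle, radians
    theta0 <- -pi / 2                   # pointing toward smaller row index
    # smooth boundary irregularity: low-order random Fourier components
    a <- runif(3, 0, 0.12); ph <- runif(3, 0, 2 * pi)
    # filopodia: narrow radial bumps
    n_fil <- sample(4:7, 1)
    th_fil <- runif(n_fil, theta0 - fan_half, theta0 + fan_half)
    amp_fil <- runif(n_fil, 0.25, 0.5)
    wid_fil <- runif(n_fil, 0.02, 0.05)

    cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
    cy <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
    dx <- cx - bx; dy <- cy - by
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    dth <- ((th - theta0 + pi) %% (2 * pi)) - pi
    rho <- r0 * (0.62 +
                   a[1] * sin(2 * dth + ph[1]) +
                   a[2] * sin(3 * dth + ph[2]) +
                   a[3] * sin(5 * dth + ph[3]))
    for (i in seq_len(n_fil)) {
      rho <- rho + r0 * amp_fil[i] *
        exp(-0.5 * ((dth - (th_fil[i] - theta0)) / wid_fil[i])^2)
    }
    mask <- (abs(dth) <= fan_half & r <= rho) | r < 0.75
    # keep a 2 px clear margin; clipping by the (convex) frame preserves
    # star-convexity about the base, hence connectivity
    mask[cx < 2 | cx > nc - 2 | cy < 2 | cy > nr - 2] <- FALSE
    mask[ceiling(by), ceiling(bx)] <- TRUE
    cell_geometry(mask, pixel_size_nm = pixel_size_nm,
                  base_point_nm = c(bx, by) * pixel_size_nm,
                  kind = "growth_cone")
  })
}

#' Sample translation events from an inhomogeneous Poisson process
#'
#' Event times follow the profile's piecewise rate (thinning against the peak
#' rate); positions are drawn over the mask proportional to `spatial_weight`,
#' uniformly jittered within each pixel. Each event receives a flash duration
#' (truncated-exponential, see [flash_kinetics()]) and the corresponding
#' expected photon budget.
#'
#' @param profile A [rate_profile()].
#' @param geometry A [cell_geometry()] providing the mask and pixel size.
#' @param duration_s Length of the simulated interval `[0, duration_s)`.
#' @param seed Integer RNG seed.
#' @param kinetics A [flash_kinetics()].
#' @param spatial_weight Optional non-negative matrix (mask grid) weighting
#'   event positions; zero outside the mask. Default: uniform over the mask.
#' @return Ground-truth tibble with columns `event_id, true_x_nm, true_y_nm,
#'   true_t_s, true_duration_s, true_photons`.
#' @export
sample_events <- function(profile, geometry, duration_s, seed,
                          kinetics = flash_kinetics(),
                          spatial_weight = NULL) {
  stopifnot(inherits(profile, "smti_rate_profile"),
            inherits(geometry, "smti_cell_geometry"))
  check_number(duration_s, "duration_s", lower = 0)
  w <- spatial_weight %||% (geometry$mask * 1)
  if (!all(dim(w) == dim(geometry$mask))) {
    abort("`spatial_weight` must share the mask grid.")
  }
  w <- w * geometry$mask
  if (any(w < 0)) abort("`spatial_weight` must be non-negative.")
  if (sum(w) <= 0) abort("`spatial_weight` is zero everywhere on the mask.")

  empty <- tibble::tibble(
    event_id = integer(), true_x_nm = double(), true_y_nm = double(),
    true_t_s = double(), true_duration_s = double(), true_photons = double()
  )
  rmax <- max(profile$baseline_rate_per_min, profile$stimulated_rate_per_min)
  if (rmax <= 0 || duration_s <= 0) return(empty)

  px <- geometry$pixel_size_nm
  with_seed(seed, {
    n_prop <- rpois(1, rmax / 60 * duration_s)
    t_prop <- sort(runif(n_prop, 0, duration_s))
    keep <- runif(n_prop) < profile_rate_per_min(profile, t_prop) / rmax
    t_ev <- t_prop[keep]
    n <- length(t_ev)
    if (n == 0) {
      empty
    } else {
      # positions: pick pixels ~ weight, jitter uniformly within the pixel
      idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
      row <- ((idx - 1) %% nrow(w)) + 1
      col <- ((idx - 1) %/% nrow(w)) + 1
      x <- (col - 1 + runif(n)) * px
      y <- (row - 1 + runif(n)) * px
      # truncated-exponential flash durations (cap at 5x the mean)
      m <- kinetics$mean_flash_duration_s
      dur <- if (m > 0) {
        -m * log(1 - runif(n) * (1 - exp(-5)))
      } else {
        rep(0, n)
      }
      tibble::tibble(
        event_id = seq_len(n), true_x_nm = x, true_y_nm = y, true_t_s = t_ev,
        true_duration_s = dur,
        true_photons = kinetics$photon_rate_per_s * dur
      )
    }
  })
}

# Integrated 2-D Gaussian PSF: fraction of a unit flash falling in each pixel
# of rows `rows`, cols `cols` (1-based), for a center (x0, y0) in px units.
psf_pixel_fractions <- function(rows, cols, x0_px, y0_px, sigma_px) {
  gx <- pnorm((cols - x0_px) / sigma_px) - pnorm((cols - 1 - x0_px) / sigma_px)
  gy <- pnorm((rows - y0_px) / sigma_px) - pnorm((rows - 1 - y0_px) / sigma_px)
  outer(gy, gx)
}

#' Render a ground-truth event table into an EMCCD movie
#'
#' Each event contributes an integrated 2-D Gaussian whose per-frame photon
#' expectation is proportional to the overlap of its emission interval with
#' the frame interval. The noise chain models an EMCCD: Poisson photon shot
#' noise, electron-multiplication excess noise (Gamma with shape equal to the
#' photon draw, expressed in the photon-equivalent domain), then additive
#' Gaussian read noise, integer rounding and clipping at zero. In `noiseless`
#' mode the expected ADC image is returned unperturbed (useful for flux
#' checks).
#'
#' @param truth Ground-truth tibble from [sample_events()].
#' @param kinetics A [flash_kinetics()]; its maturation delay shifts the
#'   emission window relative to the synthesis time.
#' @param camera A [camera_model()].
#' @param grid_shape `c(rows, cols)` of the frames.
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed.
#' @param psf_sigma_nm Gaussian PSF standard deviation, nm (must be at least
#'   0.25 px to avoid aliasing).
#' @param background_photons_per_px Uniform autofluorescence background,
#'   expected photons per pixel per frame.
#' @param noiseless If TRUE, return expected ADC values with no noise.
#' @param stimulus_time_s Stored on the returned movie for downstream use.
#' @return An [smti_movie()].
#' @export
render_movie <- function(truth, kinetics, camera, grid_shape, n_frames, seed,
                         psf_sigma_nm = 130, background_photons_per_px = 0,
                         noiseless = FALSE, stimulus_time_s = NULL) {
  stopifnot(inherits(kinetics, "smti_flash_kinetics"),
            inherits(camera, "smti_camera"))
  px <- camera$pixel_size_nm
  sigma_px <- psf_sigma_nm / px
  if (sigma_px < 0.25) {
    abort("`psf_sigma_nm` below 0.25 px would alias; refine the grid instead.")
  }
  nr <- grid_shape[1]; nc <- grid_shape[2]
  exposure <- camera$exposure_s
  t_end <- n_frames * exposure
  if (nrow(truth) > 0) {
    emit_start <- truth$true_t_s + kinetics$maturation_delay_s
    if (any(emit_start < 0 | emit_start > t_end)) {
      abort("Event emission times fall outside the rendered movie.")
    }
  }

  # expected photon image per frame
  mu <- array(background_photons_per_px, dim = c(n_frames, nr, nc))
  halo <- ceiling(4 * sigma_px + 2)
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      t0 <- truth$true_t_s[i] + kinetics$maturation_delay_s
      t1 <- t0 + truth$true_duration_s[i]
      if (truth$true_duration_s[i] <= 0) next
      k0 <- max(floor(t0 / exposure), 0)
      k1 <- min(ceiling(t1 / exposure) - 1, n_frames - 1)
      if (k1 < k0) next
      x0 <- truth$true_x_nm[i] / px
      y0 <- truth$true_y_nm[i] / px
      rows <- max(1, floor(y0 - halo)):min(nr, ceiling(y0 + halo))
      cols <- max(1, floor(x0 - halo)):min(nc, ceiling(x0 + halo))
      frac <- psf_pixel_fractions(rows, cols, x0, y0, sigma_px)
      rate <- kinetics$photon_rate_per_s
      for (k in k0:k1) {
        overlap <- min(t1, (k + 1) * exposure) - max(t0, k * exposure)
        if (overlap <= 0) next
        mu[k + 1, rows, cols] <- mu[k + 1, rows, cols] + rate * overlap * frac
      }
    }
  }

  if (noiseless) {
    frames <- camera$offset_adc + camera$adc_per_photon * mu
  } else {
    frames <- with_seed(seed, {
      n_phot <- array(rpois(length(mu), mu), dim = dim(mu))
      # EM-multiplication excess noise: Gamma(shape = n, scale = 1) in the
      # photon-equivalent domain (the gain cancels in adc_per_photon)
      amplified <- array(0, dim = dim(mu))
      pos <- n_phot > 0
      amplified[pos] <- rgamma(sum(pos), shape = n_phot[pos], scale = 1)
      adc <- camera$offset_adc + camera$adc_per_photon * amplified +
        rnorm(length(mu), 0, camera$read_noise_adc)
      array(pmin(pmax(round(adc), 0), 65535), dim = dim(mu))
    })
  }
  smti_movie(frames, camera, start_time_s = 0,
             stimulus_time_s = stimulus_time_s)
}

#' Simulate a complete SMTI acquisition
#'
#' Convenience wrapper: builds a growth-cone mask, samples ground-truth
#' events over it, and renders the EMCCD movie, all from one config and one
#' master seed (per-stage seeds are derived deterministically).
#'
#' @param config An `smti_config` (see [default_config()]).
#' @param seed Master seed; defaults to `config$seed`.
#' @return A list with elements `movie`, `truth`, `geometry`, `profile`,
#'   `kinetics`.
#' @export
simulate_movie <- function(config = default_config(), seed = config$seed) {
  cfg <- validate_config(config)
  cam <- config_camera(cfg)
  sim <- cfg$simulate
  geometry <- make_growth_cone_mask(
    derive_seed(seed, "simulate"), grid_shape = sim$grid_shape,
    pixel_size_nm = cam$pixel_size_nm
  )
  profile <- rate_profile(
    baseline_rate_per_min = sim$baseline_rate_per_min,
    stimulated_rate_per_min = sim$stimulated_rate_per_min,
    stimulus_time_s = sim$stimulus_time_s,
    onset_delay_s = sim$onset_delay_s,
    decay_time_s = sim$decay_time_s
  )
  kinetics <- flash_kinetics(
    mean_flash_duration_s = sim$mean_flash_duration_s,
    photon_rate_per_s = sim$photon_rate_per_s,
    maturation_delay_s = sim$maturation_delay_s
  )
  duration_s <- sim$n_frames * cam$exposure_s
  truth <- sample_events(profile, geometry, duration_s,
                         seed = derive_seed(seed, "events"),
                         kinetics = kinetics)
  movie <- render_movie(
    truth, kinetics, cam, grid_shape = sim$grid_shape,
    n_frames = sim$n_frames, seed = derive_seed(seed, "render"),
    psf_sigma_nm = sim$psf_sigma_nm,
    background_photons_per_px = sim$background_photons_per_px,
    stimulus_time_s = sim$stimulus_time_s
  )
  list(movie = movie, truth = truth, geometry = geometry,
       profile = profile, kinetics = kinetics)
}
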