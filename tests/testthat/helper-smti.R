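# Shared fixtures and helpers for the smti test suite. All fixtures are
# generated in code; nothing is read from disk.

test_camera <- function(...) camera_model(...)

# localize_movie without its progress message
localize_quiet <- function(movie, params = detection_params()) {
  suppressMessages(localize_movie(movie, params))
}

empty_truth <- function() {
  tibble::tibble(
    event_id = integer(), true_x_nm = double(), true_y_nm = double(),
    true_t_s = double(), true_duration_s = double(), true_photons = double()
  )
}

# a single ground-truth event row
truth_row <- function(x_nm, y_nm, t_s, duration_s, photons) {
  tibble::tibble(
    event_id = 1L, true_x_nm = x_nm, true_y_nm = y_nm, true_t_s = t_s,
    true_duration_s = duration_s, true_photons = photons
  )
}

# random localization table for round-trip / property tests
random_locs <- function(n, seed) {
  withr_seed(seed)
  cam <- camera_model()
  tibble::tibble(
    frame = sort(sample.int(50, n, replace = TRUE)) - 1L,
    x_nm = runif(n, 0, 96 * 118),
    y_nm = runif(n, 0, 96 * 118),
    photons = runif(n, 1, 2000),
    adc_sum = NA_real_, background = runif(n, 0, 5),
    sigma_nm = runif(n, 80, 250), loglik = rnorm(n, 100, 50)
  ) |>
    dplyr::mutate(adc_sum = photons * cam$adc_per_photon)
}

# set the RNG without leaking state control into package functions
withr_seed <- function(seed) set.seed(seed)

# render a single spot with EMCCD noise in a small patch; returns the ADC
# matrix and the true center (px units, patch corner origin)
render_spot_patch <- function(n_photons, bg_photons, w = 7,
                              sigma_px = 130 / 118, cam = camera_model(),
                              center = NULL) {
  if (is.null(center)) {
    center <- c(w / 2 + runif(1, -0.5, 0.5), w / 2 + runif(1, -0.5, 0.5))
  }
  mu <- matrix(bg_photons, w, w) +
    n_photons * smti:::psf_pixel_fractions(1:w, 1:w, center[1], center[2],
                                           sigma_px)
  n <- matrix(rpois(w * w, mu), w, w)
  amp <- matrix(0, w, w)
  pos <- n > 0
  amp[pos] <- rgamma(sum(pos), shape = n[pos], scale = 1)
  patch <- pmax(round(cam$offset_adc + cam$adc_per_photon * amp +
                        rnorm(w * w, 0, cam$read_noise_adc)), 0)
  list(patch = patch, center = center)
}

# Exhaustive grid-search MLE over spot position at fixed sigma, profiling
# photons N and background b at each grid node; the independent oracle for
# the iterative fit. Coarse 0.05 px scan over the patch interior, then a
# 0.01 px scan around the coarse optimum. The profiled likelihood of a
# single-spot patch is unimodal, so this equals a full 0.01 px scan.
grid_search_mle <- function(patch, cam, sigma_px) {
  w <- nrow(patch)
  y <- pmax((patch - cam$offset_adc) / cam$adc_per_photon, 0)
  yv <- as.numeric(y)
  # profile the Poisson likelihood over (N, b) at a fixed spot position by
  # damped Newton iterations (closed-form gradient and Hessian)
  profile_nll <- function(x0, y0) {
    g <- as.numeric(smti:::psf_pixel_fractions(1:w, 1:w, x0, y0, sigma_px))
    N <- max(sum(yv) - w * w * min(yv), 1)
    b <- max(min(yv), 1e-3)
    for (it in 1:40) {
      mu <- pmax(b + N * g, 1e-12)
      r <- yv / mu - 1
      gN <- sum(r * g); gb <- sum(r)
      q <- yv / mu^2
      hNN <- -sum(q * g^2); hNb <- -sum(q * g); hbb <- -sum(q)
      det <- hNN * hbb - hNb^2
      if (!is.finite(det) || abs(det) < 1e-300) break
      dN <- -(hbb * gN - hNb * gb) / det
      db <- -(-hNb * gN + hNN * gb) / det
      step <- 1
      while ((N + step * dN <= 0 || b + step * db <= 0) && step > 1e-6) {
        step <- step / 2
      }
      N <- N + step * dN
      b <- b + step * db
      if (abs(step * dN) < 1e-8 * max(N, 1) && abs(step * db) < 1e-10) break
    }
    mu <- pmax(b + N * g, 1e-12)
    c(sum(mu) - sum(yv * log(mu)), N, b)
  }
  scan <- function(xs, ys) {
    best <- c(Inf, NA, NA, NA, NA)
    for (x0 in xs) {
      for (y0 in ys) {
        r <- profile_nll(x0, y0)
        if (r[1] < best[1]) best <- c(r[1], x0, y0, r[2], r[3])
      }
    }
    best
  }
  s1 <- scan(seq(1.5, w - 1.5, by = 0.25), seq(1.5, w - 1.5, by = 0.25))
  s2 <- scan(seq(s1[2] - 0.3, s1[2] + 0.3, by = 0.05),
             seq(s1[3] - 0.3, s1[3] + 0.3, by = 0.05))
  s3 <- scan(seq(s2[2] - 0.06, s2[2] + 0.06, by = 0.01),
             seq(s2[3] - 0.06, s2[3] + 0.06, by = 0.01))
  list(x0_px = s3[2], y0_px = s3[3], photons = s3[4],
       background = s3[5], nll = s3[1])
}

# disk-shaped geometry centered on a base point (for Sholl tests)
disk_geometry <- function(radius_px = 20, grid = 64, px = 118,
                          center_px = c(grid / 2, grid / 2)) {
  cx <- matrix(rep(seq_len(grid) - 0.5, each = grid), grid, grid)
  cy <- matrix(rep(seq_len(grid) - 0.5, times = grid), grid, grid)
  mask <- (cx - center_px[1])^2 + (cy - center_px[2])^2 <= radius_px^2
  cell_geometry(mask, pixel_size_nm = px,
                base_point_nm = center_px * px, kind = "growth_cone")
}

# events tibble from bare coordinates
make_events <- function(x_nm, y_nm, t_start_s = NULL, photons = 500) {
  n <- length(x_nm)
  tibble::tibble(
    event_id = seq_len(n), x_nm = x_nm, y_nm = y_nm,
    t_start_s = t_start_s %||% rep(0, n),
    n_frames = rep(1L, n),
    total_photons = rep_len(photons, n),
    member_ids = as.character(seq_len(n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
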