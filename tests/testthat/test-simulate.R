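test_that("growth-cone masks are deterministic, connected to a boundary base point, and sized sanely", {
  g1 <- make_growth_cone_mask(7)
  g2 <- make_growth_cone_mask(7)
  expect_identical(g1$mask, g2$mask)
  expect_identical(g1$base_point_nm, g2$base_point_nm)
  expect_false(identical(g1$mask, make_growth_cone_mask(8)$mask))

  for (seed in 1:5) {
    g <- make_growth_cone_mask(seed)
    frac <- sum(g$mask) / length(g$mask)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.60)
    # base point lies on the mask boundary: inside (or touching) the mask,
    # with a background pixel center within ~1 px
    expect_true(events_in_mask(
      tibble::tibble(x_nm = g$base_point_nm[1], y_nm = g$base_point_nm[2]),
      g, dilate_px = 1
    ))
    bg <- which(!g$mask, arr.ind = TRUE)
    px <- g$pixel_size_nm
    d_bg <- sqrt(((bg[, 2] - 0.5) * px - g$base_point_nm[1])^2 +
                   ((bg[, 1] - 0.5) * px - g$base_point_nm[2])^2)
    expect_lt(min(d_bg), 1.5 * px)
  }
  expect_error(make_growth_cone_mask(1, grid_shape = c(16, 16)), "32")
})

test_that("event sampling follows the programmed Poisson process", {
  g <- disk_geometry()
  silent <- rate_profile(0, 0, stimulus_time_s = NULL)
  expect_identical(nrow(sample_events(silent, g, 60, seed = 1)), 0L)

  # determinism and containment
  pr <- rate_profile(15, 15, stimulus_time_s = NULL)
  a <- sample_events(pr, g, 60, seed = 42)
  b <- sample_events(pr, g, 60, seed = 42)
  expect_identical(a, b)
  expect_true(all(events_in_mask(
    dplyr::rename(a, x_nm = true_x_nm, y_nm = true_y_nm), g)))
  expect_true(all(a$true_t_s >= 0 & a$true_t_s < 60))
  expect_true(all(a$true_duration_s <= 5 * 0.4 + 1e-12))
  expect_equal(a$true_photons, 1250 * a$true_duration_s)

  # Monte-Carlo mean of a constant 15/min process over 60 s
  counts <- vapply(1:300, function(s) {
    nrow(sample_events(pr, g, 60, seed = 1000 + s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 300))

  # step 15 -> 30 at t = 60 s: the post-step window holds ~30 events
  step <- rate_profile(15, 30, stimulus_time_s = 60, onset_delay_s = 0,
                       decay_time_s = Inf)
  post <- vapply(1:400, function(s) {
    ev <- sample_events(step, g, 120, seed = 2000 + s)
    sum(ev$true_t_s >= 60)
  }, numeric(1))
  expect_lt(abs(mean(post) - 30), 3 * sqrt(30 / 400))
})

test_that("spatial weighting is respected and zero weight rejected", {
  g <- disk_geometry()
  pr <- rate_profile(60, 60, stimulus_time_s = NULL)
  w <- g$mask * 0
  expect_error(sample_events(pr, g, 60, seed = 1, spatial_weight = w),
               "zero")
  # all weight on the left half: every event lands there
  w <- g$mask * 1
  w[, 33:64] <- 0
  ev <- sample_events(pr, g, 120, seed = 3, spatial_weight = w)
  expect_gt(nrow(ev), 50)
  expect_true(all(ev$true_x_nm < 33 * 118))
})

test_that("noiseless rendering conserves photon flux", {
  cam <- camera_model(offset_adc = 100, read_noise_adc = 0)
  kin <- flash_kinetics()
  # blank: every pixel equals the offset
  blank <- render_movie(empty_truth(), kin, cam, c(32, 32), 3, seed = 1,
                        noiseless = TRUE)
  expect_true(all(blank$frames == 100))

  # several events away from edges: integrated ADC above offset matches
  # adc_per_photon * total photons to < 1e-3 relative
  set.seed(5)
  n <- 5
  tr <- tibble::tibble(
    event_id = seq_len(n),
    true_x_nm = runif(n, 10, 22) * 118, true_y_nm = runif(n, 10, 22) * 118,
    true_t_s = runif(n, 0.1, 1.5), true_duration_s = runif(n, 0.05, 0.4)
  )
  tr$true_photons <- 1250 * tr$true_duration_s
  m <- render_movie(tr, kin, cam, c(32, 32), 10, seed = 2, noiseless = TRUE)
  flux <- sum(m$frames - 100) / cam$adc_per_photon
  expect_lt(abs(flux - sum(tr$true_photons)) / sum(tr$true_photons), 1e-3)
})

test_that("a 400 ms flash at 200 ms exposure splits photons 1:1 across two frames", {
  cam <- camera_model(offset_adc = 0, read_noise_adc = 0, exposure_s = 0.2)
  tr <- truth_row(16 * 118, 16 * 118, t_s = 0.2, duration_s = 0.4,
                  photons = 500)
  m <- render_movie(tr, flash_kinetics(), cam, c(32, 32), 4, seed = 1,
                    noiseless = TRUE)
  per_frame <- apply(m$frames, 1, sum) / cam$adc_per_photon
  expect_equal(per_frame[1], 0)
  expect_equal(per_frame[4], 0)
  expect_equal(per_frame[2], per_frame[3], tolerance = 1e-9)
  expect_equal(per_frame[2] + per_frame[3], 500, tolerance = 1e-3)
})

test_that("rendering is deterministic per seed and guards against PSF aliasing", {
  cam <- camera_model()
  tr <- truth_row(16 * 118, 16 * 118, 0.1, 0.3, 375)
  m1 <- render_movie(tr, flash_kinetics(), cam, c(32, 32), 3, seed = 9)
  m2 <- render_movie(tr, flash_kinetics(), cam, c(32, 32), 3, seed = 9)
  m3 <- render_movie(tr, flash_kinetics(), cam, c(32, 32), 3, seed = 10)
  expect_identical(m1$frames, m2$frames)
  expect_false(identical(m1$frames, m3$frames))
  expect_error(
    render_movie(tr, flash_kinetics(), cam, c(32, 32), 3, seed = 1,
                 psf_sigma_nm = 20),
    "alias"
  )
})

test_that("EMCCD noise matches the excess-noise moment laws", {
  # flat field at 60 expected photons/px: mean = offset + c * mu,
  # var = 2 mu c^2 (EM excess noise) + read noise variance, within 10%
  cam <- camera_model(offset_adc = 100, read_noise_adc = 5)
  mu <- 60
  m <- render_movie(empty_truth(), flash_kinetics(), cam, c(128, 128), 1,
                    seed = 21, background_photons_per_px = mu)
  v <- as.numeric(m$frames)
  expect_gt(length(v), 1e4)
  expect_lt(abs(mean(v) - (100 + 13.4 * mu)) / (13.4 * mu), 0.02)
  var_expected <- 2 * mu * 13.4^2 + 5^2
  expect_lt(abs(var(v) - var_expected) / var_expected, 0.10)
})
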