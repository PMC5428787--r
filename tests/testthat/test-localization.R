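test_that("candidate detection finds spots and ignores flat frames", {
  cam <- camera_model()
  p <- detection_params()
  blank <- matrix(100, 48, 48)
  expect_identical(nrow(detect_candidates(blank, p)), 0L)
  expect_error(detect_candidates(matrix(-1, 8, 8), p), "non-negative")

  # one rendered 500-photon spot with full noise -> exactly one candidate
  # within 1 px of the truth
  set.seed(31)
  tr <- truth_row(24.3 * 118, 20.7 * 118, 0.0, 0.2, 500)
  m <- render_movie(tr, flash_kinetics(photon_rate_per_s = 2500), cam,
                    c(48, 48), 1, seed = 4, background_photons_per_px = 0.5)
  cand <- detect_candidates(m$frames[1, , ], p)
  expect_identical(nrow(cand), 1L)
  expect_lt(abs(cand$col - 0.5 - 24.3), 1)
  expect_lt(abs(cand$row - 0.5 - 20.7), 1)

  # two spots 10 px apart -> two candidates
  tr2 <- dplyr::bind_rows(
    truth_row(15 * 118, 24 * 118, 0, 0.2, 500),
    truth_row(25 * 118, 24 * 118, 0, 0.2, 500)
  )
  tr2$event_id <- 1:2
  m2 <- render_movie(tr2, flash_kinetics(photon_rate_per_s = 2500), cam,
                     c(48, 48), 1, seed = 6, background_photons_per_px = 0.5)
  expect_identical(nrow(detect_candidates(m2$frames[1, , ], p)), 2L)
})

test_that("MLE fit recovers noiseless spots essentially exactly", {
  cam <- camera_model(offset_adc = 100, read_noise_adc = 0)
  w <- 7
  g <- smti:::psf_pixel_fractions(1:w, 1:w, w / 2, w / 2, 130 / 118)
  patch <- 100 + 13.4 * (2 + 500 * g)
  fit <- fit_gaussian_mle(patch, cam)
  expect_identical(nrow(fit), 1L)
  expect_lt(abs(fit$x_nm / 118 - w / 2), 1e-3)
  expect_lt(abs(fit$y_nm / 118 - w / 2), 1e-3)
  expect_lt(abs(fit$photons - 500) / 500, 0.01)
  expect_lt(abs(fit$background - 2), 0.05)
  expect_equal(fit$adc_sum, fit$photons * 13.4)

  # off-center noiseless spot: position recovered to well under 0.01 px
  g2 <- smti:::psf_pixel_fractions(1:w, 1:w, 4.27, 2.81, 130 / 118)
  fit2 <- fit_gaussian_mle(100 + 13.4 * (1 + 800 * g2), cam)
  expect_lt(abs(fit2$x_nm / 118 - 4.27), 0.01)
  expect_lt(abs(fit2$y_nm / 118 - 2.81), 0.01)
})

test_that("iterative MLE agrees with the exhaustive grid-search oracle", {
  # small-n spot check of the oracle-equivalence property (the acceptance
  # suite runs the full version): noisy patches, both optimizers evaluated
  # at the generating PSF width
  cam <- camera_model()
  sigma_px <- 130 / 118
  set.seed(17)
  for (i in 1:12) {
    sp <- render_spot_patch(runif(1, 200, 2000), runif(1, 1, 5), cam = cam)
    fit <- fit_gaussian_mle(sp$patch, cam,
                            init = list(x0_px = 3.5, y0_px = 3.5,
                                        photons = 500, background = 2,
                                        sigma_px = sigma_px),
                            params = detection_params(),
                            sigma_bounds_px = c(sigma_px, sigma_px))
    oracle <- grid_search_mle(sp$patch, cam, sigma_px)
    expect_lt(abs(fit$x_nm / 118 - oracle$x0_px), 0.05)
    expect_lt(abs(fit$y_nm / 118 - oracle$y0_px), 0.05)
    expect_lt(abs(fit$photons - oracle$photons) / oracle$photons, 0.02)
    # no localization outside the fitting window
    expect_true(fit$x_nm >= 0 && fit$x_nm <= 7 * 118)
    expect_true(fit$y_nm >= 0 && fit$y_nm <= 7 * 118)
  }
})

test_that("localize_movie composes per-frame detection and fitting", {
  cam <- camera_model()
  tr <- truth_row(20.4 * 118, 18.6 * 118, 0, 0.2, 500)
  m <- render_movie(tr, flash_kinetics(photon_rate_per_s = 2500), cam,
                    c(40, 40), 1, seed = 8, background_photons_per_px = 0.5)
  locs <- localize_quiet(m)
  expect_identical(nrow(locs), 1L)
  expect_identical(locs$frame, 0L)
  expect_lt(abs(locs$x_nm - tr$true_x_nm), 118)
  expect_lt(abs(locs$y_nm - tr$true_y_nm), 118)
  expect_named(locs, c("frame", "x_nm", "y_nm", "photons", "adc_sum",
                       "background", "sigma_nm", "loglik"))

  # a 3-frame movie with the flash in frame 1 gives the same single fit,
  # indexed to its frame
  m3 <- smti_movie(array(rep(m$frames[1, , ], times = 3),
                         dim = c(40, 40, 3)) |> aperm(c(3, 1, 2)), cam)
  m3$frames[1, , ] <- 100
  m3$frames[3, , ] <- 100
  locs3 <- localize_quiet(m3)
  expect_identical(unique(locs3$frame), 1L)
})

test_that("false detections surviving the photon threshold and mask crop are rare", {
  # zero-event movie at default settings: the detector itself over-detects
  # by design; QC-grade false positives (photon-thresholded, in-mask) must
  # stay below 1 per 100 frames
  cam <- camera_model()
  g <- make_growth_cone_mask(19, grid_shape = c(64, 64))
  m <- render_movie(empty_truth(), flash_kinetics(), cam, c(64, 64), 150,
                    seed = 23, background_photons_per_px = 0.5)
  locs <- localize_quiet(m)
  ev <- link_localizations(locs, camera = cam)
  ev <- ev[ev$total_photons >= 30, , drop = FALSE]
  ev <- ev[events_in_mask(ev, g, dilate_px = 1), , drop = FALSE]
  expect_lt(nrow(ev) / 150, 1 / 100)
})

test_that("well-separated simulated flashes are recovered near their true positions", {
  cam <- camera_model()
  kin <- flash_kinetics(mean_flash_duration_s = 0.4)
  # 12 bright flashes on a grid, staggered in time
  xs <- rep(seq(8, 40, by = 10), 3)[1:12]
  ys <- rep(seq(8, 28, by = 10), each = 4)[1:12]
  tr <- tibble::tibble(
    event_id = 1:12, true_x_nm = (xs + 0.3) * 118, true_y_nm = (ys - 0.2) * 118,
    true_t_s = seq(0.05, by = 1.0, length.out = 12),
    true_duration_s = 0.35, true_photons = 1250 * 0.35
  )
  m <- render_movie(tr, kin, cam, c(48, 48), 70, seed = 12,
                    background_photons_per_px = 0.5)
  locs <- localize_quiet(m)
  ev <- link_localizations(locs, camera = cam)
  ev <- ev[ev$total_photons >= 30, , drop = FALSE]
  v <- validate_against_truth(ev, tr, match_radius_nm = 118)
  expect_gte(v$recall, 0.95)
  expect_lt(v$rmse_nm, 60)
})
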