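test_that("rate course handles empty input and uniform event trains", {
  span <- c(0, 60)
  empty <- rate_time_course(make_events(numeric(0), numeric(0)),
                            window_s = 10, step_s = 1, t_span = span)
  expect_true(all(empty$rate_per_s == 0))
  expect_true(all(empty$cumulative_count == 0))

  ev <- make_events(x_nm = rep(0, 60), y_nm = rep(0, 60),
                    t_start_s = seq(0.5, 59.5, by = 1))
  rc <- rate_time_course(ev, window_s = 10, step_s = 1, t_span = span)
  interior <- rc$time_s >= 5 & rc$time_s <= 55
  expect_equal(unique(rc$rate_per_s[interior]), 1.0)
  expect_true(all(diff(rc$cumulative_count) >= 0))
  expect_equal(max(rc$cumulative_count), 60)
  expect_error(rate_time_course(ev, 10, 1, t_span = c(10, 10)), "interval")
  expect_error(rate_time_course(ev, 1, 10, t_span = span), "window_s")
})

test_that("rate-curve integral over the span matches the event count", {
  set.seed(12)
  for (rep in 1:4) {
    n <- 40
    ev <- make_events(rep(0, n), rep(0, n),
                      t_start_s = sort(runif(n, 10, 110)))
    rc <- rate_time_course(ev, window_s = 10, step_s = 1, t_span = c(0, 120))
    integral <- sum(rc$rate_per_s) * 1
    expect_lt(abs(integral - n) / n, 0.01)
  }
})

test_that("density maps are conserving histograms with optional smoothing", {
  g <- disk_geometry()
  one <- make_events(10.5 * 118, 20.5 * 118)
  dm <- density_map(one, g, bin_size_nm = 118, kernel_sigma_nm = 0,
                    duration_s = 10)
  expect_equal(sum(dm$grid > 0), 1L)
  expect_equal(max(dm$grid), 0.1)
  expect_equal(dm$grid[21, 11], 0.1)

  set.seed(3)
  pr <- rate_profile(200, 200, stimulus_time_s = NULL)
  evs <- sample_events(pr, g, 60, seed = 31)
  ev <- dplyr::rename(evs, x_nm = true_x_nm, y_nm = true_y_nm)
  ev$t_start_s <- evs$true_t_s
  for (ks in c(0, 236)) {
    dm2 <- density_map(ev, g, bin_size_nm = 118, kernel_sigma_nm = ks,
                       duration_s = 60)
    expect_equal(sum(dm2$grid) * 60, nrow(ev), tolerance = 1e-9)
    expect_true(all(dm2$grid >= 0))
  }

  # two well-separated clusters -> two local maxima at the cluster centers
  cl <- make_events(
    x_nm = c(rnorm(50, 15 * 118, 60), rnorm(50, 45 * 118, 60)),
    y_nm = c(rnorm(50, 30 * 118, 60), rnorm(50, 34 * 118, 60))
  )
  gg <- cell_geometry(matrix(TRUE, 64, 64), base_point_nm = c(1, 1) * 118,
                      kind = "cell")
  dm3 <- density_map(cl, gg, bin_size_nm = 118, kernel_sigma_nm = 236,
                     duration_s = 1)
  left <- dm3$grid[, 1:32]
  pk_l <- which(left == max(left), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk_l["col"] - 15.5), 1.5)
  expect_lt(abs(pk_l["row"] - 30.5), 1.5)
  right <- dm3$grid[, 33:64]
  pk_r <- which(right == max(right), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk_r["col"] + 32 - 45.5), 1.5)
  expect_error(density_map(cl, gg, bin_size_nm = 0, duration_s = 1),
               "bin_size_nm")
})

test_that("area-normalized rate density scales as events / time / area", {
  px <- 118
  full <- cell_geometry(matrix(TRUE, 50, 50), pixel_size_nm = px,
                        kind = "cell")
  area <- 2500 * (px / 1000)^2
  ev <- make_events(runif(10, 0, 50 * px), runif(10, 0, 50 * px))
  expect_equal(area_normalized_rate(ev, full, 10), 10 / 10 / area)

  # doubling the mask area with the same events halves the density
  half <- matrix(FALSE, 50, 50); half[, 1:25] <- TRUE
  gh <- cell_geometry(half, pixel_size_nm = px, kind = "cell")
  ev_l <- make_events(runif(10, 0, 25 * px), runif(10, 0, 50 * px))
  expect_equal(area_normalized_rate(ev_l, gh, 10),
               2 * area_normalized_rate(ev_l, full, 10))
})

test_that("pre/post comparison computes window rates and fold change", {
  ev <- make_events(rep(0, 120), rep(0, 120),
                    t_start_s = seq(0.25, 119.75, by = 1))
  rc <- rate_time_course(ev, 10, 1, t_span = c(0, 120))
  pp <- pre_post_comparison(rc, c(0, 60), c(60, 120))
  expect_equal(pp$fold_change, 1, tolerance = 1e-9)
  expect_false(pp$undefined)
  expect_error(pre_post_comparison(rc, c(0, 70), c(60, 120)), "disjoint")
  expect_error(pre_post_comparison(rc, c(-10, 0), c(60, 120)), "span")

  # empty response window -> fold change 0
  early <- make_events(rep(0, 30), rep(0, 30),
                       t_start_s = seq(1, 50, length.out = 30))
  rc2 <- rate_time_course(early, 10, 1, t_span = c(0, 120))
  pp2 <- pre_post_comparison(rc2, c(0, 55), c(70, 120))
  expect_equal(pp2$response_rate_per_s, 0)
  expect_equal(pp2$fold_change, 0)

  # zero baseline -> undefined, flagged
  late <- make_events(rep(0, 30), rep(0, 30),
                      t_start_s = seq(70, 110, length.out = 30))
  rc3 <- rate_time_course(late, 10, 1, t_span = c(0, 120))
  expect_warning(pp3 <- pre_post_comparison(rc3, c(0, 55), c(65, 120)),
                 "undefined")
  expect_true(pp3$undefined)
  expect_true(is.na(pp3$fold_change))

  expect_named(glance(pp3), c("baseline_rate_per_s", "response_rate_per_s",
                              "fold_change", "undefined"))
})

test_that("a programmed rate step is recovered at the programmed onset", {
  g <- disk_geometry()
  step <- rate_profile(15, 30, stimulus_time_s = 60, onset_delay_s = 0,
                       decay_time_s = Inf)
  folds <- c(); cps <- c()
  for (s in 1:40) {
    evs <- sample_events(step, g, 120, seed = 5000 + s)
    ev <- make_events(evs$true_x_nm, evs$true_y_nm, t_start_s = evs$true_t_s)
    rc <- rate_time_course(ev, 10, 1, t_span = c(0, 120))
    pp <- pre_post_comparison(rc, c(0, 60), c(60, 120))
    folds <- c(folds, pp$fold_change)
    # change point: split time maximizing the before/after mean-rate contrast
    cand_t <- rc$time_s[rc$time_s >= 20 & rc$time_s <= 100]
    contrast <- vapply(cand_t, function(tc) {
      mean(rc$rate_per_s[rc$time_s >= tc]) -
        mean(rc$rate_per_s[rc$time_s < tc])
    }, numeric(1))
    cps <- c(cps, cand_t[which.max(contrast)])
  }
  expect_lt(abs(mean(folds) - 2), 0.25)
  expect_lt(abs(median(cps, na.rm = TRUE) - 60), 10)
})
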