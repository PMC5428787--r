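#' Instantaneous and cumulative event-rate time course
#'
#' Sliding-window rate estimate: at each grid time `t` the rate is the number
#' of event start times in `[t - window/2, t + window/2)` intersected with
#' `t_span`, divided by the effective (overlap-corrected) window length, so
#' boundary points are unbiased. Cumulative counts are evaluated on the same
#' grid. Rates use event start times only — each event is one synthesis,
#' irrespective of how many frames its flash spanned.
#'
#' @param events Event tibble with `t_start_s`.
#' @param window_s Sliding window length, seconds (>= `step_s`).
#' @param step_s Grid spacing, seconds.
#' @param t_span Numeric `c(t0, t1)`, the analyzed interval.
#' @param stimulus_time_s Optional stimulus marker carried into plots.
#' @return A tibble of class `smti_rate_course` with columns `time_s`,
#'   `rate_per_s`, `cumulative_count`.
#' @export
rate_time_course <- function(events, window_s = 10, step_s = 1, t_span,
                             stimulus_time_s = NULL) {
  check_number(window_s, "window_s", lower = 1e-12)
  check_number(step_s, "step_s", lower = 1e-12)
  if (window_s < step_s) abort("`window_s` must be at least `step_s`.")
  stopifnot(is.numeric(t_span), length(t_span) == 2)
  if (t_span[2] <= t_span[1]) abort("`t_span` must be a non-empty interval.")
  t <- seq(t_span[1], t_span[2], by = step_s)
  ts <- events$t_start_s
  lo <- pmax(t - window_s / 2, t_span[1])
  hi <- pmin(t + window_s / 2, t_span[2])
  counts <- vapply(seq_along(t),
                   function(i) sum(ts >= lo[i] & ts < hi[i]), numeric(1))
  cum <- vapply(t, function(ti) sum(ts <= ti), numeric(1))
  out <- tibble::tibble(
    time_s = t,
    rate_per_s = counts / (hi - lo),
    cumulative_count = cum
  )
  structure(out,
            class = c("smti_rate_course", class(out)),
            window_s = window_s, step_s = step_s, t_span = t_span,
            stimulus_time_s = stimulus_time_s,
            n_events = nrow(events))
}

#' Translation density map
#'
#' 2-D histogram of event positions over the mask grid, optionally smoothed
#' with a mass-conserving Gaussian kernel, normalized by the acquisition
#' duration: values are events per second per spatial bin.
#'
#' @param events Event tibble with `x_nm`, `y_nm`.
#' @param geometry A [cell_geometry()] fixing the spatial extent.
#' @param bin_size_nm Spatial bin side, nm (default one camera pixel).
#' @param kernel_sigma_nm Gaussian smoothing scale, nm (0 = none).
#' @param duration_s Normalizing duration, seconds (> 0).
#' @return An object of class `smti_density_map`: list with `grid`
#'   (rows x cols matrix, events/s), `bin_size_nm`, `duration_s`,
#'   `kernel_sigma_nm`, `geometry`.
#' @export
density_map <- function(events, geometry, bin_size_nm = 118,
                        kernel_sigma_nm = 236, duration_s) {
  stopifnot(inherits(geometry, "smti_cell_geometry"))
  check_number(bin_size_nm, "bin_size_nm", lower = 1e-12)
  check_number(kernel_sigma_nm, "kernel_sigma_nm", lower = 0)
  check_number(duration_s, "duration_s", lower = 1e-12)
  ext_x <- ncol(geometry$mask) * geometry$pixel_size_nm
  ext_y <- nrow(geometry$mask) * geometry$pixel_size_nm
  nbx <- ceiling(ext_x / bin_size_nm)
  nby <- ceiling(ext_y / bin_size_nm)
  grid <- matrix(0, nby, nbx)
  if (nrow(events) > 0) {
    bx <- pmin(pmax(floor(events$x_nm / bin_size_nm) + 1, 1), nbx)
    by <- pmin(pmax(floor(events$y_nm / bin_size_nm) + 1, 1), nby)
    for (i in seq_along(bx)) grid[by[i], bx[i]] <- grid[by[i], bx[i]] + 1
  }
  if (kernel_sigma_nm > 0 && sum(grid) > 0) {
    grid <- gaussian_blur(grid, kernel_sigma_nm / bin_size_nm,
                          conserve_mass = TRUE)
  }
  structure(
    list(grid = grid / duration_s, bin_size_nm = bin_size_nm,
         duration_s = duration_s, kernel_sigma_nm = kernel_sigma_nm,
         geometry = geometry),
    class = "smti_density_map"
  )
}

#' @export
print.smti_density_map <- function(x, ...) {
  cat(sprintf(
    "<smti_density_map> %d x %d bins of %g nm, peak %.3g events/s over %g s\n",
    nrow(x$grid), ncol(x$grid), x$bin_size_nm, max(x$grid), x$duration_s
  ))
  invisible(x)
}

#' Area-normalized translation rate density
#'
#' Event rate inside the mask normalized to the cell surface, in
#' events/s/um^2, making differently sized cells comparable.
#'
#' @param events Event tibble.
#' @param geometry A [cell_geometry()].
#' @param duration_s Acquisition duration, seconds.
#' @return A single number, events/s/um^2.
#' @export
area_normalized_rate <- function(events, geometry, duration_s) {
  check_number(duration_s, "duration_s", lower = 1e-12)
  area <- mask_area_um2(geometry)
  if (area <= 0) abort("Mask area is zero.")
  sum(events_in_mask(events, geometry)) / duration_s / area
}

#' Compare event rates before and after a stimulus
#'
#' Mean sliding-window rate over two disjoint windows of a rate course and
#' their ratio (fold change). A zero baseline leaves the fold change
#' undefined (flagged, `NA`); a zero response gives fold change 0.
#'
#' @param course A [rate_time_course()] result.
#' @param baseline_window,response_window Numeric `c(t0, t1)` intervals,
#'   disjoint and inside the course's time span.
#' @return An object of class `smti_pre_post`: list with `baseline_rate_per_s`,
#'   `response_rate_per_s`, `fold_change`, `undefined`.
#' @export
pre_post_comparison <- function(course, baseline_window, response_window) {
  stopifnot(inherits(course, "smti_rate_course"))
  bw <- baseline_window; rw <- response_window
  stopifnot(is.numeric(bw), length(bw) == 2, is.numeric(rw), length(rw) == 2)
  if (max(bw[1], rw[1]) < min(bw[2], rw[2])) {
    abort("Baseline and response windows must be disjoint.")
  }
  span <- attr(course, "t_span")
  if (bw[1] < span[1] || bw[2] > span[2] ||
      rw[1] < span[1] || rw[2] > span[2]) {
    abort("Comparison windows must lie inside the course's time span.")
  }
  mean_rate <- function(w) {
    sel <- course$time_s >= w[1] & course$time_s < w[2]
    if (!any(sel)) abort("A comparison window contains no grid points.")
    mean(course$rate_per_s[sel])
  }
  base <- mean_rate(bw)
  resp <- mean_rate(rw)
  undefined <- base == 0
  if (undefined && resp > 0) {
    warn("Baseline rate is zero; fold change undefined.")
  }
  fold <- if (undefined) NA_real_ else resp / base
  structure(
    list(baseline_rate_per_s = base, response_rate_per_s = resp,
         fold_change = fold, undefined = undefined,
         baseline_window = bw, response_window = rw),
    class = "smti_pre_post"
  )
}

#' @export
print.smti_pre_post <- function(x, ...) {
  cat(sprintf(
    "<smti_pre_post> baseline %.4g /s, response %.4g /s, fold change %s\n",
    x$baseline_rate_per_s, x$response_rate_per_s,
    ifelse(x$undefined, "undefined", sprintf("%.3g", x$fold_change))
  ))
  invisible(x)
}
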