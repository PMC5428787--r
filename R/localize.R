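#' Detection and fitting parameters
#'
#' @param smoothing_sigma_px Scale of the band-pass pre-filter (difference of
#'   Gaussians at `sigma` and `2.5 sigma`), pixels. Match it to the PSF width.
#' @param detect_threshold_adc Minimum band-passed peak height, ADC counts.
#'   The default was calibrated on simulated acquisitions to recover faint
#'   (tens-of-photons) flashes while keeping false positives rare.
#' @param window_px Odd side length of the square fitting window (>= 5).
#' @param max_iterations Iteration cap for the likelihood optimizer.
#' @param convergence_tol Projected-gradient tolerance declaring convergence.
#' @return An object of class `smti_detection_params`.
#' @export
detection_params <- function(smoothing_sigma_px = 1.1,
                             detect_threshold_adc = 20, window_px = 7L,
                             max_iterations = 200L, convergence_tol = 1e-6) {
  check_number(smoothing_sigma_px, "smoothing_sigma_px", lower = 0.1)
  check_number(detect_threshold_adc, "detect_threshold_adc", lower = 1e-12)
  check_number(window_px, "window_px", lower = 5)
  if (window_px %% 2 == 0) abort("`window_px` must be odd.")
  check_number(max_iterations, "max_iterations", lower = 1)
  check_number(convergence_tol, "convergence_tol", lower = 0)
  structure(
    list(
      smoothing_sigma_px = smoothing_sigma_px,
      detect_threshold_adc = detect_threshold_adc,
      window_px = as.integer(window_px),
      max_iterations = as.integer(max_iterations),
      convergence_tol = convergence_tol
    ),
    class = "smti_detection_params"
  )
}

# Separable Gaussian blur with edge renormalization, via banded row/column
# smoothing matrices (grids here are small, <= a few hundred px).
blur_matrix <- function(n, sigma, conserve_mass = FALSE) {
  radius <- max(1L, ceiling(3 * sigma))
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  k <- exp(-0.5 * (d / sigma)^2)
  k[abs(d) > radius] <- 0
  if (conserve_mass) {
    sweep(k, 2, colSums(k), "/") # columns sum to 1: total mass preserved
  } else {
    k / rowSums(k)               # rows sum to 1: flat fields stay flat
  }
}

gaussian_blur <- function(img, sigma, conserve_mass = FALSE) {
  kr <- blur_matrix(nrow(img), sigma, conserve_mass)
  kc <- blur_matrix(ncol(img), sigma, conserve_mass)
  kr %*% img %*% t(kc)
}

# Chebyshev-disk maximum filter via shifted pmax.
max_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (dr in -radius:radius) {
    rows <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      cols <- pmin(pmax(seq_len(nc) + dc, 1), nc)
      out <- pmax(out, img[rows, cols, drop = FALSE])
    }
  }
  out
}

#' Detect candidate flash positions in one frame
#'
#' Applies a difference-of-Gaussians band-pass (which removes the camera
#' offset and slowly varying background), finds local maxima exceeding
#' `detect_threshold_adc`, and suppresses non-maxima within the fitting
#' window. Equal-height adjacent maxima are resolved in favor of the
#' lexicographically smallest pixel.
#'
#' @param frame 2-D matrix of ADC counts.
#' @param params A [detection_params()].
#' @return Tibble with integer pixel coordinates `row`, `col` (1-based) and
#'   the band-passed `response`; zero rows when nothing exceeds threshold.
#' @export
detect_candidates <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame))
  if (any(!is.finite(frame)) || any(frame < 0)) {
    abort("`frame` must be finite and non-negative.")
  }
  s <- params$smoothing_sigma_px
  bp <- gaussian_blur(frame, s) - gaussian_blur(frame, 2.5 * s)
  radius <- params$window_px %/% 2
  is_peak <- bp >= max_filter(bp, radius) & bp > params$detect_threshold_adc
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(row = integer(), col = integer(),
                          response = double()))
  }
  cand <- tibble::tibble(row = idx[, 1], col = idx[, 2],
                         response = bp[idx])
  cand <- cand[order(-cand$response, cand$row, cand$col), ]
  # greedy non-maximum suppression within the window
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i)
    if (length(later) == 0) next
    clash <- abs(cand$row[later] - cand$row[i]) <= radius &
      abs(cand$col[later] - cand$col[i]) <= radius
    keep[later[clash]] <- FALSE
  }
  out <- cand[keep, ]
  out[order(out$row, out$col), ]
}

# Negative Poisson log-likelihood (and gradient) of the integrated-Gaussian
# spot model mu = b + N * gy %*% t(gx) on a photon-equivalent patch `y`.
# theta = (x0_px, y0_px, N, b, sigma_px); patch coordinates have the window's
# outer corner at (0, 0).
spot_nll <- function(theta, y) {
  w <- nrow(y)
  x0 <- theta[1]; y0 <- theta[2]; N <- theta[3]; b <- theta[4]
  sg <- theta[5]
  edges <- 0:w
  px_u <- (edges[-1] - x0) / sg; px_l <- (edges[-(w + 1)] - x0) / sg
  py_u <- (edges[-1] - y0) / sg; py_l <- (edges[-(w + 1)] - y0) / sg
  gx <- pnorm(px_u) - pnorm(px_l)
  gy <- pnorm(py_u) - pnorm(py_l)
  mu <- b + N * outer(gy, gx)
  mu <- pmax(mu, 1e-12)
  sum(mu) - sum(y * log(mu))
}

spot_nll_grad <- function(theta, y) {
  w <- nrow(y)
  x0 <- theta[1]; y0 <- theta[2]; N <- theta[3]; b <- theta[4]
  sg <- theta[5]
  edges <- 0:w
  px_u <- (edges[-1] - x0) / sg; px_l <- (edges[-(w + 1)] - x0) / sg
  py_u <- (edges[-1] - y0) / sg; py_l <- (edges[-(w + 1)] - y0) / sg
  gx <- pnorm(px_u) - pnorm(px_l)
  gy <- pnorm(py_u) - pnorm(py_l)
  dgx_dx0 <- (dnorm(px_l) - dnorm(px_u)) / sg
  dgy_dy0 <- (dnorm(py_l) - dnorm(py_u)) / sg
  dgx_ds <- (px_l * dnorm(px_l) - px_u * dnorm(px_u)) / sg
  dgy_ds <- (py_l * dnorm(py_l) - py_u * dnorm(py_u)) / sg
  g2 <- outer(gy, gx)
  mu <- pmax(b + N * g2, 1e-12)
  wres <- 1 - y / mu # d NLL / d mu
  c(
    sum(wres * N * outer(gy, dgx_dx0)),
    sum(wres * N * outer(dgy_dy0, gx)),
    sum(wres * g2),
    sum(wres),
    sum(wres * N * (outer(dgy_ds, gx) + outer(gy, dgx_ds)))
  )
}

#' Fit one flash by Gaussian maximum likelihood
#'
#' Maximizes the Poisson likelihood of the photon-equivalent counts (ADC
#' minus offset, divided by the ADC-per-photon conversion, floored at zero)
#' under the model `b + N * IntegratedGaussian(x0, y0, sigma)` using bounded
#' quasi-Newton iterations with an analytic gradient. `sigma` is fitted
#' freely within `[0.5, 3]` px. The electron-multiplication excess-noise
#' factor is deliberately ignored during fitting (standard SMLM practice; it
#' inflates localization errors by ~sqrt(2) but leaves the estimates
#' unbiased).
#'
#' @param patch Square ADC matrix (`window_px` x `window_px`).
#' @param camera A [camera_model()].
#' @param init Optional list with `x0_px`, `y0_px`, `photons`, `background`,
#'   `sigma_px`; defaults to a centroid/median-border initialization.
#' @param params A [detection_params()] (iteration cap and tolerance).
#' @param sigma_bounds_px Lower/upper bounds on the fitted PSF width in
#'   pixels; set both to the known PSF width for a fixed-sigma fit.
#' @return One-row localization tibble in *patch* coordinates (nm from the
#'   patch's outer corner) plus a `converged` flag, or a zero-row tibble when
#'   the fit fails (non-convergence or non-positive photons).
#' @export
fit_gaussian_mle <- function(patch, camera, init = NULL,
                             params = detection_params(),
                             sigma_bounds_px = c(0.5, 3)) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch),
            inherits(camera, "smti_camera"))
  w <- nrow(patch)
  y <- pmax((patch - camera$offset_adc) / camera$adc_per_photon, 0)

  if (is.null(init)) {
    border <- c(y[1, ], y[w, ], y[, 1], y[, w])
    b0 <- max(median(border), 1e-3)
    resid <- pmax(y - b0, 0)
    tot <- sum(resid)
    if (tot > 0) {
      cols <- matrix(rep(seq_len(w) - 0.5, each = w), w, w)
      rows <- matrix(rep(seq_len(w) - 0.5, times = w), w, w)
      x0 <- sum(cols * resid) / tot
      y0 <- sum(rows * resid) / tot
    } else {
      x0 <- y0 <- w / 2
    }
    init <- list(x0_px = x0, y0_px = y0, photons = max(tot, 1),
                 background = b0, sigma_px = 1.1)
  }
  theta0 <- c(init$x0_px, init$y0_px, init$photons, init$background,
              init$sigma_px)
  lower <- c(0, 0, 1e-3, 1e-6, sigma_bounds_px[1])
  upper <- c(w, w, 1e7, 1e5, sigma_bounds_px[2])
  theta0 <- pmin(pmax(theta0, lower), upper)
  fit <- tryCatch(
    optim(theta0, spot_nll, gr = spot_nll_grad, y = y,
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = params$max_iterations,
                         pgtol = params$convergence_tol,
                         factr = 1e5)),
    error = function(e) NULL
  )
  failed <- is.null(fit) || fit$convergence != 0 || fit$par[3] <= 0
  if (failed) {
    out <- empty_localizations()
    out$converged <- logical(0)
    return(out)
  }
  px <- camera$pixel_size_nm
  tibble::tibble(
    frame = NA_integer_,
    x_nm = fit$par[1] * px, y_nm = fit$par[2] * px,
    photons = fit$par[3],
    adc_sum = fit$par[3] * camera$adc_per_photon,
    background = fit$par[4],
    sigma_nm = fit$par[5] * px,
    loglik = -fit$value,
    converged = fit$convergence == 0
  )
}

#' Localize all flashes in a movie
#'
#' Runs per-frame candidate detection and MLE fitting, concatenating the
#' results ordered by `(frame, x_nm)`. Candidates whose fit fails to converge
#' or returns non-positive photons are discarded; per-movie candidate and
#' failure totals are reported as a message.
#'
#' @param movie An [smti_movie()].
#' @param params A [detection_params()].
#' @return Localization tibble with columns
#'   `frame, x_nm, y_nm, photons, adc_sum, background, sigma_nm, loglik`.
#' @export
localize_movie <- function(movie, params = detection_params()) {
  stopifnot(inherits(movie, "smti_movie"))
  cam <- movie$camera
  px <- cam$pixel_size_nm
  w <- params$window_px
  radius <- w %/% 2
  nf <- n_frames(movie)
  nr <- dim(movie$frames)[2]; nc <- dim(movie$frames)[3]
  n_cand <- 0L; n_fail <- 0L
  per_frame <- vector("list", nf)
  for (k in seq_len(nf)) {
    frame <- movie$frames[k, , ]
    cand <- detect_candidates(frame, params)
    n_cand <- n_cand + nrow(cand)
    if (nrow(cand) == 0) next
    fits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      # clamp the window inside the frame
      r0 <- min(max(cand$row[i] - radius, 1), nr - w + 1)
      c0 <- min(max(cand$col[i] - radius, 1), nc - w + 1)
      patch <- frame[r0:(r0 + w - 1), c0:(c0 + w - 1)]
      fit <- fit_gaussian_mle(patch, cam, params = params)
      if (nrow(fit) == 0) {
        n_fail <- n_fail + 1L
        next
      }
      fit$frame <- k - 1L # 0-based frames
      fit$x_nm <- fit$x_nm + (c0 - 1) * px
      fit$y_nm <- fit$y_nm + (r0 - 1) * px
      fits[[i]] <- fit
    }
    per_frame[[k]] <- dplyr::bind_rows(fits)
  }
  locs <- dplyr::bind_rows(per_frame)
  if (nrow(locs) == 0) {
    locs <- empty_localizations()
  } else {
    locs <- locs[order(locs$frame, locs$x_nm), loc_columns]
  }
  inform(sprintf(
    "localize: %d frames, %d candidates, %d fit failures, %d localizations",
    nf, n_cand, n_fail, nrow(locs)
  ))
  locs
}
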