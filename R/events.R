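#' Calibrate the photon threshold from manually selected flashes
#'
#' Mirrors the manual calibration workflow: a set of per-flash photon budgets
#' from hand-picked, unambiguous reporter flashes is summarized by its
#' arithmetic mean, which becomes the photon threshold; the sample standard
#' deviation is returned for reporting.
#'
#' @param flash_photon_sums Numeric vector of per-flash photon budgets
#'   (>= 3 values, all positive).
#' @return A list with `threshold_photons`, `sd_photons`, `n`.
#' @examples
#' calibrate_threshold(c(450, 500, 550))$threshold_photons # 500
#' @export
calibrate_threshold <- function(flash_photon_sums) {
  x <- as.numeric(flash_photon_sums)
  if (length(x) < 3) abort("Need at least 3 flash photon budgets.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("All flash photon budgets must be positive.")
  }
  list(threshold_photons = mean(x), sd_photons = sd(x), n = length(x))
}

#' Filter localizations by photon count
#'
#' Keeps exactly the localizations with `photons >= threshold_photons`
#' (inclusive comparison); input order is preserved.
#'
#' @param locs Localization tibble.
#' @param threshold_photons Threshold, photons (>= 0).
#' @return The surviving rows.
#' @export
apply_photon_threshold <- function(locs, threshold_photons) {
  check_number(threshold_photons, "threshold_photons", lower = 0)
  locs[locs$photons >= threshold_photons, , drop = FALSE]
}

#' Link localizations across frames into translation events
#'
#' Greedy chronological nearest-neighbor linking, recombining the photons a
#' single reporter emits over consecutive frames: a localization joins an
#' open track if it lies within `search_radius_nm` of the track's
#' photon-weighted mean position and within `max_gap_frames` frames of the
#' track's last localization; assignment conflicts are resolved by nearest
#' distance. Every localization ends up in exactly one event; an event's
#' position is the photon-weighted mean of its members, its photons their
#' sum, and its start time the frame-start time of its first member.
#'
#' @param locs Localization tibble sorted by frame.
#' @param search_radius_nm Linking radius, nm (default 236 = 2 px).
#' @param max_gap_frames Maximum frame gap bridged by a track (default 1,
#'   i.e. only consecutive frames link).
#' @param camera A [camera_model()] supplying the frame-to-time mapping.
#' @param start_time_s Acquisition start time.
#' @return Event tibble `event_id, x_nm, y_nm, t_start_s, n_frames,
#'   total_photons, member_ids` (member row indices joined by `;`).
#' @export
link_localizations <- function(locs, search_radius_nm = 236,
                               max_gap_frames = 1,
                               camera = camera_model(),
                               start_time_s = 0) {
  check_number(search_radius_nm, "search_radius_nm", lower = 0)
  check_number(max_gap_frames, "max_gap_frames", lower = 0)
  if (nrow(locs) == 0) return(empty_events())
  if (is.unsorted(locs$frame)) abort("`locs` must be sorted by frame.")

  ids <- seq_len(nrow(locs))
  # open track state
  tracks <- list() # each: x, y, photons, last_frame, first_frame, members
  closed <- list()
  for (f in sort(unique(locs$frame))) {
    # close tracks that can no longer be extended
    if (length(tracks) > 0) {
      expire <- vapply(tracks, function(tr) f - tr$last_frame > max_gap_frames,
                       logical(1))
      closed <- c(closed, tracks[expire])
      tracks <- tracks[!expire]
    }
    in_frame <- which(locs$frame == f)
    if (length(tracks) > 0 && length(in_frame) > 0) {
      # candidate (localization, track) pairs within the search radius
      pairs <- expand.grid(li = seq_along(in_frame), ti = seq_along(tracks))
      d <- sqrt(
        (locs$x_nm[in_frame[pairs$li]] -
           vapply(tracks, `[[`, numeric(1), "x")[pairs$ti])^2 +
          (locs$y_nm[in_frame[pairs$li]] -
             vapply(tracks, `[[`, numeric(1), "y")[pairs$ti])^2
      )
      ok <- d <= search_radius_nm
      pairs <- pairs[ok, , drop = FALSE]
      d <- d[ok]
      assigned_loc <- rep(FALSE, length(in_frame))
      used_track <- rep(FALSE, length(tracks))
      for (j in order(d)) {
        li <- pairs$li[j]; ti <- pairs$ti[j]
        if (assigned_loc[li] || used_track[ti]) next
        assigned_loc[li] <- TRUE
        used_track[ti] <- TRUE
        i <- in_frame[li]
        tr <- tracks[[ti]]
        wsum <- tr$photons + locs$photons[i]
        if (wsum > 0) {
          tr$x <- (tr$x * tr$photons + locs$x_nm[i] * locs$photons[i]) / wsum
          tr$y <- (tr$y * tr$photons + locs$y_nm[i] * locs$photons[i]) / wsum
        }
        tr$photons <- wsum
        tr$last_frame <- f
        tr$members <- c(tr$members, ids[i])
        tracks[[ti]] <- tr
      }
      new_idx <- in_frame[!assigned_loc]
    } else {
      new_idx <- in_frame
    }
    for (i in new_idx) {
      tracks[[length(tracks) + 1]] <- list(
        x = locs$x_nm[i], y = locs$y_nm[i], photons = locs$photons[i],
        first_frame = f, last_frame = f, members = ids[i]
      )
    }
  }
  closed <- c(closed, tracks)
  if (length(closed) == 0) return(empty_events())
  ev <- purrr::map_dfr(closed, function(tr) {
    tibble::tibble(
      x_nm = tr$x, y_nm = tr$y,
      t_start_s = frame_time(tr$first_frame, camera, start_time_s),
      n_frames = as.integer(tr$last_frame - tr$first_frame + 1L),
      total_photons = tr$photons,
      member_ids = paste(tr$members, collapse = ";")
    )
  })
  ev <- ev[order(ev$t_start_s, ev$x_nm), ]
  ev$event_id <- seq_len(nrow(ev))
  ev[, c("event_id", "x_nm", "y_nm", "t_start_s", "n_frames",
         "total_photons", "member_ids")]
}

#' Crop events to a rectangular region of interest
#'
#' Keeps events whose center lies in the half-open rectangle
#' `[xmin, xmax) x [ymin, ymax)` (an event exactly on the low edge is kept,
#' on the high edge dropped), the tight rectangular windows drawn around
#' growth cones.
#'
#' @param events Event tibble.
#' @param roi Numeric `c(xmin, xmax, ymin, ymax)` in nm.
#' @return The surviving events.
#' @export
crop_to_roi <- function(events, roi) {
  stopifnot(is.numeric(roi), length(roi) == 4)
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) {
    abort("`roi` must have positive area: c(xmin, xmax, ymin, ymax).")
  }
  keep <- events$x_nm >= roi[1] & events$x_nm < roi[2] &
    events$y_nm >= roi[3] & events$y_nm < roi[4]
  events[keep, , drop = FALSE]
}
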