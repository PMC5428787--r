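#' Write a localization table
#'
#' Plain-text CSV with one header line and columns
#' `frame,x_nm,y_nm,photons,adc_sum,background,sigma_nm,loglik`
#' (`frame` is 0-based). Values round-trip to better than 1e-6 relative.
#'
#' @param locs Localization tibble (see [localize_movie()]).
#' @param path Output path.
#' @export
write_localizations <- function(locs, path) {
  locs <- tibble::as_tibble(locs)
  missing <- setdiff(loc_columns, names(locs))
  if (length(missing) > 0) {
    abort(paste0("Localization table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(locs[loc_columns], path)
  invisible(path)
}

#' Read a localization table
#'
#' @param path CSV written by [write_localizations()] (or any table with the
#'   same header).
#' @return A localization tibble.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(sprintf("No localization table at '%s'.", path))
  locs <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(loc_columns, names(locs))
  if (length(missing) > 0) {
    abort(paste0("Malformed localization table header; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(locs) > 0 && any(locs$photons < 0)) {
    abort("Localization table contains negative photon counts.")
  }
  locs$frame <- as.integer(locs$frame)
  tibble::as_tibble(locs[loc_columns])
}

#' Write / read translation-event tables
#'
#' CSV with columns `event_id,x_nm,y_nm,t_start_s,n_frames,total_photons,
#' member_ids`; `member_ids` stores the constituent localization row indices
#' joined by `;`.
#'
#' @param events Event tibble (see [link_localizations()]).
#' @param path File path.
#' @export
write_events <- function(events, path) {
  events <- tibble::as_tibble(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("No event table at '%s'.", path))
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(member_ids = readr::col_character()))
  ev$event_id <- as.integer(ev$event_id)
  ev$n_frames <- as.integer(ev$n_frames)
  tibble::as_tibble(ev)
}

#' Write / read simulator ground-truth tables
#'
#' CSV with columns `event_id,true_x_nm,true_y_nm,true_t_s,true_duration_s,
#' true_photons`.
#'
#' @param truth Ground-truth tibble (see [sample_events()]).
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(tibble::as_tibble(truth), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort(sprintf("No ground-truth table at '%s'.", path))
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
}
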