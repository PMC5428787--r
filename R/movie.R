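#' SMTI movie container
#'
#' A movie is a stack of single-channel frames of raw ADC counts plus the
#' camera model needed to interpret them. Frames are stored as an integer
#' array indexed `[frame, row, column]`; pixel `(row r, col c)` covers
#' `x in [(c-1), c] * pixel_size_nm`, `y in [(r-1), r] * pixel_size_nm`, so
#' pixel centers sit at half-integer multiples of the pixel size.
#'
#' @param frames 3-D numeric array `[frame, row, col]` of non-negative counts,
#'   or a single matrix (treated as one frame).
#' @param camera A [camera_model()].
#' @param start_time_s Acquisition start time (seconds).
#' @param stimulus_time_s Optional time at which a treatment was added.
#' @return An object of class `smti_movie`.
#' @export
smti_movie <- function(frames, camera, start_time_s = 0,
                       stimulus_time_s = NULL) {
  stopifnot(inherits(camera, "smti_camera"))
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1, nrow(frames), ncol(frames)))
  }
  if (length(dim(frames)) != 3) {
    abort("`frames` must be a [frame, row, col] array or a single matrix.")
  }
  if (dim(frames)[1] < 1) abort("A movie needs at least one frame.")
  if (any(frames < 0)) abort("ADC counts must be non-negative.")
  structure(
    list(
      frames = frames, camera = camera, start_time_s = start_time_s,
      stimulus_time_s = stimulus_time_s
    ),
    class = "smti_movie"
  )
}

#' @export
print.smti_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<smti_movie> %d frames of %d x %d px, %g s/frame (%.1f s total)\n",
    d[1], d[2], d[3], x$camera$exposure_s, d[1] * x$camera$exposure_s
  ))
  invisible(x)
}

#' @export
dim.smti_movie <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie An [smti_movie()].
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Read a movie from a multi-frame TIFF stack
#'
#' Reads a single-channel 16-bit grayscale stack; counts are loaded unmodified
#' as integers. Multi-channel (RGB) input is rejected.
#'
#' @param path Path to a TIFF stack.
#' @param camera A [camera_model()] describing the acquisition.
#' @param start_time_s,stimulus_time_s Passed to [smti_movie()].
#' @return An [smti_movie()].
#' @export
read_movie <- function(path, camera, start_time_s = 0,
                       stimulus_time_s = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read movie: no file at '%s'.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) abort("TIFF stack contains zero frames.")
  if (length(dim(pages[[1]])) != 2) {
    abort("Expected single-channel grayscale frames; got multi-channel data.")
  }
  frames <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  inform(sprintf("Read %d frames of %d x %d px from '%s'.",
                 dim(frames)[1], dim(frames)[2], dim(frames)[3], path))
  smti_movie(frames, camera, start_time_s = start_time_s,
             stimulus_time_s = stimulus_time_s)
}

#' Write a movie as a 16-bit multi-frame TIFF stack
#'
#' Counts are clipped to the 16-bit range and rounded; a round trip through
#' [read_movie()] is bit-identical for integer counts in `[0, 65535]`.
#'
#' @param movie An [smti_movie()].
#' @param path Output path.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "smti_movie"))
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- pmin(pmax(round(movie$frames[k, , ]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a binary mask from a single-frame TIFF
#'
#' Any strictly positive pixel is foreground.
#' @param path Path to a single-frame grayscale TIFF.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read mask: no file at '%s'.", path))
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.list(img)) {
    if (length(img) != 1) abort("Mask TIFF must have exactly one frame.")
    img <- img[[1]]
  }
  if (length(dim(img)) != 2) abort("Mask must be single-channel grayscale.")
  img > 0
}

#' Write a binary mask as a single-frame TIFF
#' @param mask Logical (or 0/1) matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
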