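#' Cell geometry: mask, outline and Sholl base point
#'
#' Shared container for the segmented cell shape. The mask raster must share
#' the movie's pixel grid; the outline polygon (in nm) is derived from the
#' mask border. The base point anchors Sholl arcs for growth cones.
#'
#' @param mask Logical matrix (TRUE = inside the cell), same grid as the movie.
#' @param pixel_size_nm Pixel size of the mask raster, nm.
#' @param base_point_nm Numeric length-2 `c(x, y)` in nm, or NULL. Required
#'   for `kind = "growth_cone"`; must lie inside or on the mask.
#' @param kind `"growth_cone"` or `"cell"`.
#' @param outline Optional polygon (data frame with `x_nm`, `y_nm`);
#'   derived from the mask border when NULL.
#' @return An object of class `smti_cell_geometry`.
#' @export
cell_geometry <- function(mask, pixel_size_nm = 118, base_point_nm = NULL,
                          kind = c("growth_cone", "cell"), outline = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  mask <- mask > 0
  if (!any(mask)) abort("`mask` has no foreground pixels.")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  if (kind == "growth_cone" && is.null(base_point_nm)) {
    abort("Growth-cone geometry requires a `base_point_nm`.")
  }
  if (!is.null(base_point_nm)) {
    stopifnot(is.numeric(base_point_nm), length(base_point_nm) == 2)
    if (!point_in_mask(base_point_nm[1], base_point_nm[2], mask,
                       pixel_size_nm, dilate = 1)) {
      abort("`base_point_nm` must lie inside or on the mask (within 1 px).")
    }
  }
  if (is.null(outline)) outline <- mask_outline(mask, pixel_size_nm)
  structure(
    list(
      mask = mask, pixel_size_nm = pixel_size_nm,
      base_point_nm = base_point_nm, kind = kind, outline = outline
    ),
    class = "smti_cell_geometry"
  )
}

#' @export
print.smti_cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<smti_cell_geometry> %s, %d x %d px grid, area %.1f um^2\n",
    x$kind, nrow(x$mask), ncol(x$mask), mask_area_um2(x)
  ))
  invisible(x)
}

# Is point (x, y) nm inside the mask? `dilate` expands the test by that many
# pixels so border points count as inside.
point_in_mask <- function(x_nm, y_nm, mask, pixel_size_nm, dilate = 0) {
  col <- floor(x_nm / pixel_size_nm) + 1
  row <- floor(y_nm / pixel_size_nm) + 1
  inside <- logical(length(col))
  for (d_r in -dilate:dilate) {
    for (d_c in -dilate:dilate) {
      r <- pmin(pmax(row + d_r, 1), nrow(mask))
      c <- pmin(pmax(col + d_c, 1), ncol(mask))
      inside <- inside | mask[cbind(r, c)]
    }
  }
  ok <- x_nm >= 0 & y_nm >= 0 &
    x_nm <= ncol(mask) * pixel_size_nm & y_nm <= nrow(mask) * pixel_size_nm
  inside & ok
}

#' Which events fall inside the mask?
#'
#' Events exactly on the mask border count as intracellular (the mask raster
#' is the authority).
#'
#' @param events Event tibble with `x_nm`, `y_nm`.
#' @param geometry A [cell_geometry()].
#' @param dilate_px Border tolerance in pixels: positions within this many
#'   pixels of a foreground pixel also count as inside. Use 1 when filtering
#'   fitted positions, whose localization error can push an event sitting on
#'   a one-pixel-wide filopodium just across the pixel border.
#' @return Logical vector.
#' @export
events_in_mask <- function(events, geometry, dilate_px = 0) {
  stopifnot(inherits(geometry, "smti_cell_geometry"))
  if (nrow(events) == 0) return(logical(0))
  point_in_mask(events$x_nm, events$y_nm, geometry$mask,
                geometry$pixel_size_nm, dilate = dilate_px)
}

#' Mask area in square micrometres
#' @param geometry A [cell_geometry()].
#' @export
mask_area_um2 <- function(geometry) {
  stopifnot(inherits(geometry, "smti_cell_geometry"))
  sum(geometry$mask) * (geometry$pixel_size_nm / 1000)^2
}

# Trace the mask border as a closed polygon in nm via contour following at
# the 0.5 level (marching-squares style, as grDevices implements it).
mask_outline <- function(mask, pixel_size_nm) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (all(m == m[1])) {
    # degenerate (all-foreground) mask: no interior contour exists
    return(tibble::tibble(x_nm = double(), y_nm = double(), ring = integer()))
  }
  # contourLines works in the coordinates of (x = rows, y = cols) grids;
  # supply pixel-center coordinates so the outline lands in nm space.
  xc <- (seq_len(nrow(m)) - 0.5) * pixel_size_nm # y-direction (rows)
  yc <- (seq_len(ncol(m)) - 0.5) * pixel_size_nm # x-direction (cols)
  cl <- grDevices::contourLines(x = xc, y = yc, z = m, levels = 0.5)
  if (length(cl) == 0) {
    return(tibble::tibble(x_nm = double(), y_nm = double(), ring = integer()))
  }
  purrr::map_dfr(seq_along(cl), function(i) {
    tibble::tibble(x_nm = cl[[i]]$y, y_nm = cl[[i]]$x, ring = i)
  })
}
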