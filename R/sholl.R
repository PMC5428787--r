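#' Sholl arc radii for a growth cone
#'
#' Five (by default) equidistant concentric arcs centered at the growth-cone
#' base point; the outermost arc passes through the furthest mask pixel, so
#' it circumscribes the cone. `A1` is the most central arc, `A5` the most
#' peripheral.
#'
#' @param geometry A [cell_geometry()] with a base point.
#' @param n_arcs Number of arcs (default 5).
#' @return Numeric vector of outer radii in nm, `R * (1:n)/n`.
#' @export
sholl_radii <- function(geometry, n_arcs = 5L) {
  stopifnot(inherits(geometry, "smti_cell_geometry"))
  if (is.null(geometry$base_point_nm)) {
    abort("Sholl analysis needs a base point on the geometry.")
  }
  check_number(n_arcs, "n_arcs", lower = 1)
  d <- mask_pixel_distances(geometry)
  r_max <- max(d)
  r_max * seq_len(n_arcs) / n_arcs
}

# Distances (nm) from the base point to every foreground pixel center.
mask_pixel_distances <- function(geometry) {
  idx <- which(geometry$mask, arr.ind = TRUE)
  px <- geometry$pixel_size_nm
  cx <- (idx[, 2] - 0.5) * px
  cy <- (idx[, 1] - 0.5) * px
  sqrt((cx - geometry$base_point_nm[1])^2 +
         (cy - geometry$base_point_nm[2])^2)
}

#' Count intracellular events per Sholl arc
#'
#' Events outside the mask are excluded; each remaining event joins arc `k`
#' when its base-point distance falls in `((k-1) R/n, k R/n]` (half-open on
#' the inner edge, closed on the outer, so the furthest event lands exactly
#' in the outermost arc; distance 0 belongs to `A1`). Events marginally
#' beyond the outermost radius — possible because radii are measured to
#' pixel centers while the mask extends half a pixel further — are clamped
#' into the outermost arc. Per-arc mask-intersected annulus areas are
#' reported for uniformity checks.
#'
#' @param events Event tibble with `x_nm`, `y_nm`.
#' @param geometry A [cell_geometry()] with base point.
#' @param radii Radii from [sholl_radii()].
#' @return A tibble of class `smti_sholl` with one row per arc: `arc`,
#'   `r_inner_nm`, `r_outer_nm`, `count`, `percentage`, `area_um2`.
#' @export
assign_events_to_arcs <- function(events, geometry, radii) {
  stopifnot(inherits(geometry, "smti_cell_geometry"))
  if (is.unsorted(radii) || any(diff(radii) <= 0)) {
    abort("`radii` must be strictly increasing.")
  }
  n <- length(radii)
  inner <- c(0, radii[-n])
  inside <- events_in_mask(events, geometry)
  ev <- events[inside, , drop = FALSE]
  d <- sqrt((ev$x_nm - geometry$base_point_nm[1])^2 +
              (ev$y_nm - geometry$base_point_nm[2])^2)
  # epsilon guard keeps distances exactly on an arc edge in the inner arc
  # (intervals are closed on their outer edge)
  arc <- pmin(pmax(ceiling(d / radii[n] * n - 1e-9), 1L), n)
  counts <- tabulate(arc, nbins = n)
  total <- sum(counts)
  pct <- if (total > 0) counts / total * 100 else rep(NA_real_, n)
  dpix <- mask_pixel_distances(geometry)
  apix <- pmin(pmax(ceiling(dpix / radii[n] * n - 1e-9), 1L), n)
  areas <- tabulate(apix, nbins = n) * (geometry$pixel_size_nm / 1000)^2
  out <- tibble::tibble(
    arc = paste0("A", seq_len(n)),
    r_inner_nm = inner, r_outer_nm = radii,
    count = counts, percentage = pct, area_um2 = areas
  )
  structure(out,
            class = c("smti_sholl", class(out)),
            total_events = total,
            n_excluded = nrow(events) - nrow(ev),
            base_point_nm = geometry$base_point_nm)
}

#' Pool Sholl results across growth cones
#'
#' The per-arc percentages of a group can be summarized per cone then
#' averaged, or pooled (counts summed across cones first); both views are
#' returned since they answer slightly different questions.
#'
#' @param results List of [assign_events_to_arcs()] results with matching
#'   arc counts.
#' @return Tibble with `arc`, `mean_percentage` (across cones),
#'   `sem_percentage`, `pooled_percentage`, `total_count`.
#' @export
pool_sholl <- function(results) {
  stopifnot(length(results) >= 1)
  n <- nrow(results[[1]])
  pct <- do.call(rbind, lapply(results, function(r) r$percentage))
  counts <- do.call(rbind, lapply(results, function(r) r$count))
  tot <- colSums(counts)
  tibble::tibble(
    arc = results[[1]]$arc,
    mean_percentage = colMeans(pct, na.rm = TRUE),
    sem_percentage = apply(pct, 2, function(v) {
      v <- v[!is.na(v)]; if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
    }),
    pooled_percentage = if (sum(tot) > 0) tot / sum(tot) * 100 else NA_real_,
    total_count = tot
  )
}

# Mann-Whitney U statistic with mid-ranks; U counts, for group a, the pairs
# (a_i, b_j) with a_i > b_j (+ 1/2 per tie).
mw_u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Rank-based two-group comparison of per-arc percentages
#'
#' Mann-Whitney U test on one arc's per-growth-cone event percentages.
#' For combined sample sizes up to 12 the two-sided p-value is computed by
#' full enumeration of the permutation distribution of U (exact even with
#' ties, which are handled by mid-ranks); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b Lists of [assign_events_to_arcs()] results (one per
#'   growth cone), or bare numeric vectors of percentages. Cones with zero
#'   intracellular events have undefined percentages and are excluded with a
#'   warning.
#' @param arc Arc index (1 = most central) when groups are Sholl results.
#' @return An object of class `smti_mw_test`: list with `u`, `p_value`,
#'   `method`, `n_a`, `n_b`, `arc`.
#' @export
compare_arc_distributions <- function(group_a, group_b, arc = 1L) {
  pull_pct <- function(group, label) {
    if (is.numeric(group)) return(group[!is.na(group)])
    v <- vapply(group, function(r) {
      stopifnot(inherits(r, "smti_sholl"))
      r$percentage[arc]
    }, numeric(1))
    if (anyNA(v)) {
      warn(sprintf(
        "Excluding %d growth cone(s) with zero events from group %s.",
        sum(is.na(v)), label
      ))
    }
    v[!is.na(v)]
  }
  x <- pull_pct(group_a, "a")
  y <- pull_pct(group_b, "b")
  if (length(x) < 3 || length(y) < 3) {
    abort("Each group needs at least 3 growth cones with events.")
  }
  na <- length(x); nb <- length(y)
  u <- mw_u_statistic(x, y)
  mu <- na * nb / 2
  if (na + nb <= 12) {
    r <- rank(c(x, y))
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    r <- rank(c(x, y))
    nties <- table(r)
    sigma2 <- na * nb / 12 *
      ((na + nb + 1) - sum(nties^3 - nties) / ((na + nb) * (na + nb - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(2 * pnorm(-max(z, 0)), 1)
    method <- "normal approximation with tie correction"
  }
  structure(
    list(u = u, p_value = p, method = method, n_a = na, n_b = nb, arc = arc),
    class = "smti_mw_test"
  )
}

#' @export
print.smti_mw_test <- function(x, ...) {
  cat(sprintf(
    "<smti_mw_test> arc %d: U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
    x$arc, x$u, x$n_a, x$n_b, x$p_value, x$method
  ))
  invisible(x)
}
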