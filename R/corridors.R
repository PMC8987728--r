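#' Point-wise statistics across registered signals
#'
#' At each normalized arc length of the common grid, the x and y values of
#' the n signals are treated as uncorrelated normal samples: the sample
#' mean of each channel gives the characteristic average, and the sample
#' standard deviation (n - 1 denominator) quantifies spread.
#'
#' @param registered Tibble with `signal`, `s`, `x`, `y`, all signals on a
#'   common grid ([reparameterize()] or `register_signals()$registered`).
#' @return A tibble with one row per grid point: `s`, `x_mean`, `y_mean`,
#'   `x_sd`, `y_sd`.
#' @export
pointwise_stats <- function(registered) {
  if (length(unique(registered$signal)) < 2) {
    abort("Need at least 2 signals for point-wise statistics.")
  }
  registered %>%
    group_by(.data$s) %>%
    summarise(
      x_mean = mean(.data$x), y_mean = mean(.data$y),
      x_sd = sd(.data$x), y_sd = sd(.data$y),
      .groups = "drop"
    ) %>%
    arrange(.data$s)
}

#' Chi-squared quantile with two degrees of freedom
#'
#' The confidence region of an uncorrelated bivariate normal is the set
#' where the sum of the two squared standardized deviations is below the
#' chi-squared (2 dof) quantile of the desired probability `p`. With two
#' degrees of freedom the quantile has the closed form `-2 * log(1 - p)`,
#' which this function implements. The conventional "plus and minus one
#' standard deviation" corridor corresponds to a quantile of 1, i.e.
#' `p = 0.394` (39.4% of the probability mass).
#'
#' @param p Probability in `[0, 1)`.
#' @return The quantile value `-2 * log(1 - p)`.
#' @examples
#' chi2_quantile_2dof(0.394) # ~1
#' chi2_quantile_2dof(0.95) # ~5.991
#' @export
chi2_quantile_2dof <- function(p) {
  if (any(p < 0) || any(p >= 1)) {
    abort("`p` must satisfy 0 <= p < 1.")
  }
  -2 * log(1 - p)
}

#' Axis-aligned confidence ellipses at every grid point
#'
#' Each grid point's uncorrelated bivariate normal yields an axis-aligned
#' ellipse centered at the mean with semi-axes
#' `sqrt(chi2) * SD(x)` and `sqrt(chi2) * SD(y)`, where `chi2` is the
#' 2-dof chi-squared quantile of the coverage probability `p`. A zero
#' standard deviation gives a degenerate (zero-length) axis.
#'
#' @param stats Output of [pointwise_stats()].
#' @param p Coverage probability (default 0.394, the plus/minus one
#'   standard deviation corridor).
#' @return A tibble with `s`, `x_center`, `y_center`, `x_semi`, `y_semi`.
#' @export
confidence_ellipses <- function(stats, p = 0.394) {
  r <- sqrt(chi2_quantile_2dof(p))
  tibble(
    s = stats$s,
    x_center = stats$x_mean, y_center = stats$y_mean,
    x_semi = r * stats$x_sd, y_semi = r * stats$y_sd
  )
}

#' Extract the corridor envelope of a set of ellipses
#'
#' The response corridor is the envelope of all per-grid-point confidence
#' ellipses. It has no general closed form, so it is extracted numerically:
#' the scalar field `F(x, y) = min over ellipses of
#' ((x - x0)/a)^2 + ((y - y0)/b)^2` is sampled on a regular grid covering
#' every ellipse plus a margin, and the `F = 1` iso-contour is traced by
#' marching squares with linear interpolation of the cell crossings. If
#' several closed contours appear (widely separated ellipses), the one with
#' the largest enclosed area is kept with a warning. Degenerate ellipses
#' (a zero semi-axis) contribute nothing beyond their center and are
#' excluded from the field; if *all* ellipses are degenerate the envelope
#' collapses to the zero-width polyline of centers, returned with a
#' warning.
#'
#' The grid is refined adaptively: `grid_resolution` is the minimum cell
#' count per axis, and the count is increased (up to a cap of 4000) until
#' the median ellipse semi-axis on that axis spans at least two cells, so
#' that thin corridors — small between-signal spread relative to the
#' curve's overall extent — do not fall between grid lines and fragment
#' the contour.
#'
#' @param ellipses Output of [confidence_ellipses()].
#' @param grid_resolution Minimum cells per axis for the sampling grid
#'   (default 250).
#' @param margin_fraction Margin beyond the ellipse bounding box as a
#'   fraction of its extent (default 0.05).
#' @return A tibble `x`, `y` tracing a closed polygon (first vertex
#'   repeated as the last row).
#' @export
extract_envelope <- function(ellipses, grid_resolution = 250,
                             margin_fraction = 0.05) {
  live <- ellipses[ellipses$x_semi > 0 & ellipses$y_semi > 0, ]
  if (nrow(live) == 0) {
    warn("All ellipses are degenerate; returning a zero-width envelope.")
    return(tibble(
      x = c(ellipses$x_center, rev(ellipses$x_center), ellipses$x_center[1]),
      y = c(ellipses$y_center, rev(ellipses$y_center), ellipses$y_center[1])
    ))
  }
  xr <- range(live$x_center - live$x_semi, live$x_center + live$x_semi)
  yr <- range(live$y_center - live$y_semi, live$y_center + live$y_semi)
  xr <- xr + c(-1, 1) * margin_fraction * diff(xr)
  yr <- yr + c(-1, 1) * margin_fraction * diff(yr)

  n_cells <- function(rng, semi) {
    min(4000, max(grid_resolution, ceiling(diff(rng) / (median(semi) / 2))))
  }
  nx <- n_cells(xr, live$x_semi)
  ny <- n_cells(yr, live$y_semi)
  xs <- seq(xr[1], xr[2], length.out = nx + 1)
  ys <- seq(yr[1], yr[2], length.out = ny + 1)

  # background above the contour level; each ellipse only updates the
  # cells of its own bounding box
  field <- matrix(4, length(xs), length(ys))
  for (j in seq_len(nrow(live))) {
    ix <- which(abs(xs - live$x_center[j]) <= 2 * live$x_semi[j])
    iy <- which(abs(ys - live$y_center[j]) <= 2 * live$y_semi[j])
    if (length(ix) == 0 || length(iy) == 0) next
    qx <- ((xs[ix] - live$x_center[j]) / live$x_semi[j])^2
    qy <- ((ys[iy] - live$y_center[j]) / live$y_semi[j])^2
    field[ix, iy] <- pmin(field[ix, iy], outer(pmin(qx, 4), pmin(qy, 4), "+"))
  }

  contours <- grDevices::contourLines(xs, ys, field, levels = 1)
  if (length(contours) == 0) {
    abort(paste0(
      "No iso-contour found at the envelope level; ",
      "increase `grid_resolution` or `margin_fraction`."
    ))
  }
  areas <- vapply(
    contours,
    function(cl) abs(pracma::polyarea(cl$x, cl$y)),
    numeric(1)
  )
  if (length(contours) > 1) {
    warn(paste0(
      length(contours), " closed contours found; ",
      "keeping the largest-area one."
    ))
  }
  best <- contours[[which.max(areas)]]
  ring <- tibble(x = best$x, y = best$y)
  if (ring$x[1] != ring$x[nrow(ring)] || ring$y[1] != ring$y[nrow(ring)]) {
    ring <- bind_rows(ring, ring[1, ])
  }
  ring
}

#' Split a corridor envelope into inner and outer polylines
#'
#' Corridors are conventionally plotted as two open curves flanking the
#' characteristic average rather than one closed polygon. The envelope is
#' cut at its two vertices nearest to the first and last points of the
#' average; the two resulting arcs are oriented to run alongside the
#' average and labelled by their signed side relative to the average's
#' local direction of travel: the arc lying to the left is `outer`, to the
#' right `inner` (for an increasing concave force-displacement curve the
#' outer arc is the upper corridor).
#'
#' The average must lie inside the envelope up to a tolerance of about one
#' extraction-grid cell: where a standard deviation vanishes exactly (e.g.
#' every signal starts at the same origin) the end ellipse is degenerate
#' and the corridor has zero width there, leaving the average endpoint on
#' — numerically, just outside — the envelope boundary. Points farther
#' outside than `tol` indicate a genuine enclosure failure and the
#' envelope is returned unsplit in both slots with a warning.
#'
#' All nearest-vertex and side computations are carried out in
#' coordinates normalized by the envelope's per-axis extent, so the split
#' is invariant under rescaling either axis (the two axes usually carry
#' different physical units).
#'
#' @param envelope Closed polygon tibble from [extract_envelope()].
#' @param average Tibble with `x`, `y`: the characteristic average.
#' @param tol Enclosure tolerance in normalized coordinates. The default
#'   (`NULL`) uses 1% of the envelope extent or twice the average's mean
#'   vertex step, whichever is larger: where an end ellipse is degenerate
#'   the average can protrude by about one resample arc-step, which
#'   shrinks as the resample grid is refined.
#' @return A list with tibbles `inner` and `outer` and logical `split`.
#' @export
split_corridor <- function(envelope, average, tol = NULL) {
  ring <- envelope
  nr <- nrow(ring)
  if (ring$x[1] == ring$x[nr] && ring$y[1] == ring$y[nr]) {
    ring <- ring[-nr, ]
  }
  nv <- nrow(ring)

  # unit-free geometry: normalize both curves by the envelope extent
  sx <- diff(range(ring$x))
  sy <- diff(range(ring$y))
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  rx <- (ring$x - min(ring$x)) / sx
  ry <- (ring$y - min(ring$y)) / sy
  ax <- (average$x - min(ring$x)) / sx
  ay <- (average$y - min(ring$y)) / sy
  na <- length(ax)
  if (is.null(tol)) {
    step <- sum(sqrt(diff(ax)^2 + diff(ay)^2)) / (na - 1)
    tol <- max(0.01, 2 * step)
  }

  inside <- mgcv::in.out(
    as.matrix(cbind(c(rx, rx[1]), c(ry, ry[1]))),
    as.matrix(cbind(ax, ay))
  )
  if (!all(inside)) {
    # distance from each stray point to the nearest envelope vertex
    stray <- which(!inside)
    d <- vapply(stray, function(i) {
      sqrt(min((rx - ax[i])^2 + (ry - ay[i])^2))
    }, numeric(1))
    if (any(d > tol)) {
      warn("Average polyline is not enclosed by the envelope; not splitting.")
      return(list(inner = envelope, outer = envelope, split = FALSE))
    }
  }

  i1 <- which.min((rx - ax[1])^2 + (ry - ay[1])^2)
  i2 <- which.min((rx - ax[na])^2 + (ry - ay[na])^2)
  if (i1 == i2) {
    warn("Envelope cut points coincide; not splitting.")
    return(list(inner = envelope, outer = envelope, split = FALSE))
  }

  idx_forward <- if (i1 <= i2) i1:i2 else c(i1:nv, 1:i2)
  idx_backward <- if (i2 <= i1) i2:i1 else c(i2:nv, 1:i1)
  arc_a <- ring[idx_forward, ]
  arc_b <- ring[rev(idx_backward), ] # both arcs now run first -> last

  side_a <- mean(signed_side(rx[idx_forward], ry[idx_forward], ax, ay))
  side_b <- mean(signed_side(
    rx[rev(idx_backward)], ry[rev(idx_backward)], ax, ay
  ))
  if (side_a >= side_b) {
    list(inner = arc_b, outer = arc_a, split = TRUE)
  } else {
    list(inner = arc_a, outer = arc_b, split = TRUE)
  }
}

#' Densify an ellipse family along arc length
#'
#' The corridor is conceptually the envelope of a *continuous* family of
#' confidence ellipses; the grid supplies a finite sample of it. When the
#' between-signal spread is small relative to the spacing of consecutive
#' ellipse centers, the sampled union disconnects into beads that are an
#' artifact of the sampling, not of the corridor. This helper inserts
#' linearly interpolated ellipses (centers, semi-axes, and `s`) between
#' consecutive rows until each step, measured in the semi-axis units of
#' either neighboring ellipse, is at most half a radius, restoring a
#' connected band wherever the continuous family is connected. Measuring
#' the step per-axis in semi-axis units keeps the rule equivariant under
#' axis rescaling.
#'
#' @param ellipses Output of [confidence_ellipses()].
#' @param cap Maximum subdivision factor per segment (default 50), which
#'   bounds the fill-in near degenerate (zero-spread) grid points.
#' @return A tibble like `ellipses` with interpolated rows added.
#' @export
densify_ellipses <- function(ellipses, cap = 50) {
  k <- nrow(ellipses)
  if (k < 2) {
    return(ellipses)
  }
  dx <- diff(ellipses$x_center)
  dy <- diff(ellipses$y_center)
  # step length in units of each neighbor's own semi-axes; a degenerate
  # neighbor (zero semi-axis) imposes no requirement of its own
  step_units <- function(idx) {
    a <- ellipses$x_semi[idx]
    b <- ellipses$y_semi[idx]
    ifelse(a > 0 & b > 0, sqrt((dx / a)^2 + (dy / b)^2), NA_real_)
  }
  d1 <- step_units(seq_len(k - 1))
  d2 <- step_units(2:k)
  d <- pmax(d1, d2, na.rm = TRUE)
  factor <- ifelse(is.na(d) | d == 0, 1, pmin(cap, ceiling(d / 0.5)))

  pieces <- purrr::map(seq_len(k - 1), function(j) {
    if (factor[j] == 1) {
      return(ellipses[j, ])
    }
    t <- seq(0, 1, length.out = factor[j] + 1)[-(factor[j] + 1)]
    lerp <- function(col) {
      ellipses[[col]][j] + t * (ellipses[[col]][j + 1] - ellipses[[col]][j])
    }
    tibble(
      s = lerp("s"),
      x_center = lerp("x_center"), y_center = lerp("y_center"),
      x_semi = lerp("x_semi"), y_semi = lerp("y_semi")
    )
  })
  bind_rows(c(pieces, list(ellipses[k, ])))
}

# Signed side of points relative to a polyline's local direction:
# positive = left of travel. For each point, the nearest average vertex's
# (centered-difference) tangent is crossed with the offset vector.
# Operates on coordinates already normalized by the caller.
signed_side <- function(px, py, ax, ay) {
  na <- length(ax)
  tx <- c(ax[2] - ax[1], ax[3:na] - ax[1:(na - 2)], ax[na] - ax[na - 1])
  ty <- c(ay[2] - ay[1], ay[3:na] - ay[1:(na - 2)], ay[na] - ay[na - 1])
  vapply(seq_along(px), function(i) {
    d <- (ax - px[i])^2 + (ay - py[i])^2
    k <- which.min(d)
    cr <- tx[k] * (py[i] - ay[k]) - ty[k] * (px[i] - ax[k])
    sign(cr)
  }, numeric(1))
}
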