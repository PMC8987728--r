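#' Range-based scaling factors for a signal set
#'
#' Before arc length is computed, signals are scaled so that the two axes
#' are of comparable magnitude; otherwise an axis measured in large units
#' (e.g. force in N against displacement in mm) would dominate the arc
#' length and distort the re-parameterization. Each axis is divided by the
#' mean range of that axis over all signals: the divisor for x is
#' `mean(per-signal max x) - mean(per-signal min x)`, and likewise for y.
#' Using the *mean* extrema keeps the relative size of individual signals
#' intact.
#'
#' A degenerate axis (all signals constant, zero mean range) gets divisor 1
#' with a warning so constant channels remain processable.
#'
#' @param signals A signal set (see [as_signal_set()]).
#' @return An object of class `scaling_factors`: a list with the mean
#'   extrema (`x_min_bar`, `x_max_bar`, `y_min_bar`, `y_max_bar`) and the
#'   divisors (`x_divisor`, `y_divisor`).
#' @export
compute_scaling <- function(signals) {
  signals <- as_signal_set(signals)
  ext <- signals %>%
    group_by(.data$signal) %>%
    summarise(
      xmin = min(.data$x), xmax = max(.data$x),
      ymin = min(.data$y), ymax = max(.data$y),
      .groups = "drop"
    )
  f <- list(
    x_min_bar = mean(ext$xmin), x_max_bar = mean(ext$xmax),
    y_min_bar = mean(ext$ymin), y_max_bar = mean(ext$ymax)
  )
  f$x_divisor <- f$x_max_bar - f$x_min_bar
  f$y_divisor <- f$y_max_bar - f$y_min_bar
  for (ax in c("x", "y")) {
    key <- paste0(ax, "_divisor")
    if (f[[key]] <= 0) {
      warn(paste0(
        "Degenerate ", ax, " range (divisor ", format(f[[key]]),
        "); substituting divisor 1."
      ))
      f[[key]] <- 1
    }
  }
  structure(f, class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("Scaling factors (mean extrema over signals)\n")
  cat(sprintf(
    "  x: [%g, %g], divisor %g\n", x$x_min_bar, x$x_max_bar, x$x_divisor
  ))
  cat(sprintf(
    "  y: [%g, %g], divisor %g\n", x$y_min_bar, x$y_max_bar, x$y_divisor
  ))
  invisible(x)
}

#' Scale signal coordinates by range divisors
#'
#' Divides each coordinate by the corresponding divisor from
#' [compute_scaling()]. Scaled coordinates are used *only* for arc-length
#' computation; registration and statistics always operate on the original
#' unscaled data.
#'
#' @param signals A signal set or any data frame with `signal`, `x`, `y`.
#' @param factors A `scaling_factors` object.
#' @return A tibble like `signals` with `x` and `y` divided by the
#'   divisors.
#' @export
scale_signals <- function(signals, factors) {
  stopifnot(inherits(factors, "scaling_factors"))
  out <- as_tibble(signals)
  out$x <- out$x / factors$x_divisor
  out$y <- out$y / factors$y_divisor
  out
}

#' Cumulative polyline arc length
#'
#' Arc length accumulated along an ordered point sequence, assuming linear
#' segments between consecutive points: `s[1] = 0` and
#' `s[j] = s[j-1] + sqrt(dx^2 + dy^2)`.
#'
#' @param x,y Numeric coordinate vectors of equal length (at least 2).
#' @return Numeric vector of cumulative arc lengths, same length as `x`,
#'   starting at 0 and strictly increasing.
#' @examples
#' arc_length(c(0, 3), c(0, 4)) # 0, 5
#' @export
arc_length <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be equal-length vectors with at least 2 points.")
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) {
    abort("Zero-length segment found; remove duplicate consecutive points.")
  }
  c(0, cumsum(seg))
}

#' Re-parameterize a signal set by normalized arc length
#'
#' The first pipeline stage. Each signal is scaled (for arc-length purposes
#' only), its cumulative arc length is computed with linear segments and
#' normalized by the total so it spans `[0, 1]`, and the *unscaled*
#' coordinates are then resampled by piecewise-linear interpolation onto a
#' common uniform grid of `n_resample` normalized-arc-length values. After
#' this stage every signal has the same number of points at the same
#' normalized arc lengths, which point-wise statistics require; arc length
#' is monotone by construction, so hysteretic and oscillatory signals need
#' no segmentation.
#'
#' @param signals A signal set.
#' @param n_resample Number of uniform grid points on `[0, 1]` (default
#'   200; at least 2, though coarse grids under-resolve curved signals).
#' @param factors Optional precomputed `scaling_factors`; computed from
#'   `signals` when `NULL`.
#' @return A tibble with columns `signal`, `s` (normalized arc length),
#'   `x`, `y` (unscaled coordinates at `s`), carrying attributes
#'   `total_arc_length` (named vector of per-signal totals, in scaled
#'   coordinates) and `scaling` (the factors used).
#' @export
reparameterize <- function(signals, n_resample = 200, factors = NULL) {
  signals <- as_signal_set(signals)
  if (n_resample < 2) {
    abort("`n_resample` must be at least 2.")
  }
  if (is.null(factors)) {
    factors <- compute_scaling(signals)
  }
  grid <- seq(0, 1, length.out = n_resample)
  labels <- unique(signals$signal)

  totals <- numeric(length(labels))
  names(totals) <- labels
  parts <- purrr::map(labels, function(lab) {
    sig <- signals[signals$signal == lab, ]
    s <- arc_length(sig$x / factors$x_divisor, sig$y / factors$y_divisor)
    total <- s[length(s)]
    totals[[lab]] <<- total
    s_hat <- s / total
    tibble(
      signal = lab,
      s = grid,
      x = approx(s_hat, sig$x, xout = grid, ties = "ordered")$y,
      y = approx(s_hat, sig$y, xout = grid, ties = "ordered")$y
    )
  })
  out <- bind_rows(parts)
  attr(out, "total_arc_length") <- totals
  attr(out, "scaling") <- factors
  out
}
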