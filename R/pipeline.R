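#' Compute the characteristic average and response corridors
#'
#' The full three-stage pipeline:
#'
#' 1. **Arc-length re-parameterization** ([reparameterize()]): signals are
#'    scaled by the mean axis ranges, expressed as functions of normalized
#'    arc length, and resampled onto a common uniform grid — no
#'    monotonicity or shared endpoints required.
#' 2. **Registration** ([register_signals()]): optional monotone warping
#'    of arc length aligns shared features across signals (`m = 0` skips
#'    this, appropriate for monotonic data).
#' 3. **Statistics** ([pointwise_stats()], [confidence_ellipses()],
#'    [extract_envelope()], [split_corridor()]): per-grid-point means form
#'    the characteristic average; per-grid-point standard deviations form
#'    axis-aligned confidence ellipses whose envelope is the response
#'    corridor at coverage probability `p`.
#'
#' The run is deterministic for fixed inputs and settings.
#'
#' @param signals A signal set or data frame with `signal`, `x`, `y`.
#' @param n_resample Grid size for arc-length resampling (default 200).
#' @param m Interior warp control points per signal (default 0: no
#'   registration).
#' @param lambda Warping penalty factor (default `1e-2`).
#' @param p Corridor coverage probability (default 0.394, the plus/minus
#'   one standard deviation corridor).
#' @param grid_resolution Envelope extraction grid cells per axis.
#' @param margin_fraction Envelope grid margin fraction.
#' @param max_iter,tol Registration optimizer settings.
#' @param seed Stored in the result metadata and used for any stochastic
#'   component (the default pipeline is deterministic).
#' @return An object of class `corridor_result`: a list with `signals`
#'   (validated input), `average` (tibble `s`, `x`, `y`), `stats`,
#'   `ellipses`, `envelope` (closed polygon), `inner`/`outer` corridor
#'   polylines, `registration` (a `registration_result`), and `config`.
#' @examples
#' fam <- generate_monotonic(n_signals = 6, seed = 1)
#' res <- build_corridors(fam$signals)
#' glance(res)
#' @export
build_corridors <- function(signals, n_resample = 200, m = 0,
                            lambda = 1e-2, p = 0.394,
                            grid_resolution = 250, margin_fraction = 0.05,
                            max_iter = 500, tol = 1e-6, seed = NULL) {
  signals <- as_signal_set(signals)
  rp <- reparameterize(signals, n_resample = n_resample)
  reg <- register_signals(rp,
    m = m, lambda = lambda,
    max_iter = max_iter, tol = tol, seed = seed
  )
  st <- pointwise_stats(reg$registered)
  average <- tibble(s = st$s, x = st$x_mean, y = st$y_mean)
  ell <- confidence_ellipses(st, p = p)

  degenerate <- all(ell$x_semi == 0 & ell$y_semi == 0)
  if (degenerate) {
    warn("All signals identical: corridors collapse onto the average.")
    envelope <- tibble(
      x = c(average$x, rev(average$x), average$x[1]),
      y = c(average$y, rev(average$y), average$y[1])
    )
    inner <- average[, c("x", "y")]
    outer <- average[, c("x", "y")]
  } else {
    envelope <- extract_envelope(densify_ellipses(ell),
      grid_resolution = grid_resolution,
      margin_fraction = margin_fraction
    )
    sides <- split_corridor(envelope, average[, c("x", "y")])
    inner <- sides$inner
    outer <- sides$outer
  }

  structure(
    list(
      signals = signals, average = average, stats = st, ellipses = ell,
      envelope = envelope, inner = inner, outer = outer,
      registration = reg,
      config = list(
        n_resample = n_resample, m = m, lambda = lambda, p = p,
        grid_resolution = grid_resolution,
        margin_fraction = margin_fraction,
        max_iter = max_iter, tol = tol, seed = seed
      )
    ),
    class = "corridor_result"
  )
}

#' @export
print.corridor_result <- function(x, ...) {
  cfg <- x$config
  cat("Corridor result\n")
  cat(sprintf(
    "  %d signals, %d grid points, m = %d, lambda = %s, p = %.3f\n",
    n_signals(x$signals), nrow(x$average), cfg$m,
    format(cfg$lambda), cfg$p
  ))
  cat(sprintf(
    "  registration objective: %.6f -> %.6f\n",
    x$registration$score_before, x$registration$score_after
  ))
  cat(sprintf(
    "  envelope: %d vertices, area %.4g\n",
    nrow(x$envelope),
    abs(pracma::polyarea(x$envelope$x, x$envelope$y))
  ))
  invisible(x)
}

#' Tidy the curves of a corridor result
#'
#' @param x A `corridor_result`.
#' @param ... Unused.
#' @return A long tibble with columns `curve` (`"average"`, `"inner"`,
#'   `"outer"`), `s` (normalized arc length, `NA` for corridor vertices,
#'   which do not live on the grid), `x`, `y`.
#' @exportS3Method generics::tidy
tidy.corridor_result <- function(x, ...) {
  bind_rows(
    mutate(x$average, curve = "average"),
    mutate(x$inner, curve = "inner", s = NA_real_),
    mutate(x$outer, curve = "outer", s = NA_real_)
  )[, c("curve", "s", "x", "y")]
}

#' One-row summary of a corridor result
#'
#' @param x A `corridor_result`.
#' @param ... Unused.
#' @return A one-row tibble with run settings, registration scores, and
#'   the envelope area.
#' @exportS3Method generics::glance
glance.corridor_result <- function(x, ...) {
  cfg <- x$config
  tibble(
    n_signals = n_signals(x$signals),
    n_resample = cfg$n_resample,
    m = cfg$m, lambda = cfg$lambda, p = cfg$p,
    chi2_value = chi2_quantile_2dof(cfg$p),
    C_x = x$registration$C_x, C_y = x$registration$C_y,
    score_before = x$registration$score_before,
    score_after = x$registration$score_after,
    envelope_area = abs(pracma::polyarea(x$envelope$x, x$envelope$y))
  )
}
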