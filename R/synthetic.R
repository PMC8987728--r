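#' Synthetic signal families with known ground truth
#'
#' Reproducible generators for the three signal archetypes the corridor
#' method targets, each returning the generated signal set together with
#' the noise-free base curve so recovery error can be measured:
#'
#' * **monotonic**: concave force-displacement-like curves with a toe
#'   region, a quasi-linear region, and a concave-down terminal region
#'   (a smoothstep base `y = u^2 (3 - 2u)`), with per-signal endpoint and
#'   stiffness jitter — endpoints deliberately differ across signals.
#' * **oscillatory**: damped sinusoids
#'   `y(t) = A exp(-gamma t) sin(omega t + phi_i)` with per-signal phase
#'   `phi_i ~ U(-jitter, jitter)` (radians), emulating acceleration-time
#'   traces whose peaks are misaligned across subjects.
#' * **hysteretic**: load-plateau-unload loops traced parametrically
#'   (rise with an inflection into a gently sloped plateau, then an unload
#'   path returning below the loading path), non-monotonic in both axes,
#'   with per-signal amplitude jitter.
#'
#' All randomness flows from `seed` through one generator stream (signal
#' by signal: jitter draws first, then noise), so a given spec and seed
#' reproduce identical output; the caller's RNG state is left untouched.
#'
#' @param n_signals Number of signals. Defaults mirror typical study
#'   sizes for each archetype: 12 specimens (monotonic), 7 volunteers
#'   (oscillatory), 8 subjects (hysteretic).
#' @param n_points Samples per signal.
#' @param noise_sd Standard deviation of additive Gaussian y-noise.
#' @param jitter Family-specific variability scale: fractional endpoint
#'   and stiffness spread (monotonic, hysteretic) or phase half-range in
#'   radians (oscillatory).
#' @param seed Integer seed.
#' @return A list with `signals` (a `signal_set` tibble), `truth` (tibble
#'   `x`, `y`: the noise-free base curve, for the hysteretic family the
#'   base loop), and `family`.
#' @name synthetic
NULL

new_family <- function(signals, truth, family) {
  list(signals = as_signal_set(signals), truth = truth, family = family)
}

#' @rdname synthetic
#' @export
generate_monotonic <- function(n_signals = 12, n_points = 100,
                               noise_sd = 0.01, jitter = 0.15, seed = 1) {
  base <- function(u) u^2 * (3 - 2 * u) # toe / quasi-linear / concave-down
  withr::with_seed(seed, {
    parts <- purrr::map(seq_len(n_signals), function(i) {
      x_max <- 1 + jitter * stats::runif(1, -1, 1)
      amp <- 1 + jitter * stats::runif(1, -1, 1)
      x <- seq(0, x_max, length.out = n_points)
      y <- amp * base(x / x_max) + stats::rnorm(n_points, sd = noise_sd)
      tibble(signal = sprintf("mono_%02d", i), x = x, y = y)
    })
    u <- seq(0, 1, length.out = 400)
    new_family(
      bind_rows(parts),
      tibble(x = u, y = base(u)),
      "monotonic"
    )
  })
}

#' @rdname synthetic
#' @export
generate_oscillatory <- function(n_signals = 7, n_points = 400,
                                 noise_sd = 0.01, jitter = 0.6, seed = 1) {
  A <- 1
  gamma <- 1.2
  omega <- 6 * pi # three full cycles over the unit observation window
  t <- seq(0, 1, length.out = n_points)
  withr::with_seed(seed, {
    parts <- purrr::map(seq_len(n_signals), function(i) {
      phi <- stats::runif(1, -jitter, jitter)
      y <- A * exp(-gamma * t) * sin(omega * t + phi) +
        stats::rnorm(n_points, sd = noise_sd)
      tibble(signal = sprintf("osc_%02d", i), x = t, y = y)
    })
    new_family(
      bind_rows(parts),
      tibble(x = t, y = A * exp(-gamma * t) * sin(omega * t)),
      "oscillatory"
    )
  })
}

# Base load-plateau-unload loop traced by parameter u in [0, 1]:
# loading over u in [0, 0.5] (toe-rise with an inflection into a gently
# sloped plateau), unloading over u in (0.5, 1] back below the loading
# path to a residual displacement.
hysteretic_base <- function(u, x_max = 1, amp = 1, x_res = 0.35) {
  load_y <- function(v) (1 - exp(-5 * v)) + 0.1 * v
  y_peak <- load_y(1)
  loading <- u <= 0.5
  x <- ifelse(loading, 2 * u * x_max,
    x_max - (2 * u - 1) * (x_max - x_res)
  )
  y <- ifelse(loading, amp * load_y(2 * u),
    amp * y_peak * (1 - (2 * u - 1))^2.5
  )
  tibble(x = x, y = y)
}

#' @rdname synthetic
#' @export
generate_hysteretic <- function(n_signals = 8, n_points = 200,
                                noise_sd = 0.01, jitter = 0.1, seed = 1) {
  u <- seq(0, 1, length.out = n_points)
  withr::with_seed(seed, {
    parts <- purrr::map(seq_len(n_signals), function(i) {
      x_max <- 1 + jitter * stats::runif(1, -1, 1)
      amp <- 1 + jitter * stats::runif(1, -1, 1)
      curve <- hysteretic_base(u, x_max = x_max, amp = amp)
      curve$y <- curve$y + stats::rnorm(n_points, sd = noise_sd)
      curve$signal <- sprintf("hyst_%02d", i)
      curve[, c("signal", "x", "y")]
    })
    new_family(
      bind_rows(parts),
      hysteretic_base(seq(0, 1, length.out = 400)),
      "hysteretic"
    )
  })
}

#' Generate a synthetic signal family by name
#'
#' Dispatcher over [generate_monotonic()], [generate_oscillatory()], and
#' [generate_hysteretic()].
#'
#' @param family One of `"monotonic"`, `"oscillatory"`, `"hysteretic"`.
#' @param ... Passed to the family generator.
#' @return See [synthetic].
#' @export
generate_signals <- function(family = c(
                               "monotonic", "oscillatory", "hysteretic"
                             ), ...) {
  family <- match.arg(family)
  switch(family,
    monotonic = generate_monotonic(...),
    oscillatory = generate_oscillatory(...),
    hysteretic = generate_hysteretic(...)
  )
}
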