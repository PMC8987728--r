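# Independent oracles and small fixture builders used across test files.

# Monotone cubic Hermite interpolation implemented from the slope rules:
# arithmetic-mean secant slopes at interior knots, one-sided at the ends,
# projected onto the circle of radius 3 (in secant units) when needed to
# preserve monotonicity; evaluation by the closed-form cubic Hermite basis.
hermite_fc_oracle <- function(xk, yk, x) {
  nk <- length(xk)
  dx <- diff(xk)
  secant <- diff(yk) / dx
  m <- c(secant[1], (secant[-1] + secant[-(nk - 1)]) / 2, secant[nk - 1])
  for (i in seq_len(nk - 1)) {
    if (secant[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / secant[i]
      b <- m[i + 1] / secant[i]
      r2 <- a^2 + b^2
      if (r2 > 9) {
        tau <- 3 / sqrt(r2)
        m[i] <- tau * a * secant[i]
        m[i + 1] <- tau * b * secant[i]
      }
    }
  }
  vapply(x, function(xv) {
    i <- max(1, min(nk - 1, findInterval(xv, xk)))
    h <- dx[i]
    t <- (xv - xk[i]) / h
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    h00 * yk[i] + h10 * h * m[i] + h01 * yk[i + 1] + h11 * h * m[i + 1]
  }, numeric(1))
}

# Brute-force area of the union of axis-aligned ellipses by counting
# points of a fine regular grid that fall inside any ellipse.
grid_union_area <- function(ellipses, n = 900) {
  xr <- range(ellipses$x_center - ellipses$x_semi,
    ellipses$x_center + ellipses$x_semi
  )
  yr <- range(ellipses$y_center - ellipses$y_semi,
    ellipses$y_center + ellipses$y_semi
  )
  xs <- seq(xr[1], xr[2], length.out = n)
  ys <- seq(yr[1], yr[2], length.out = n)
  inside <- matrix(FALSE, n, n)
  for (j in seq_len(nrow(ellipses))) {
    qx <- ((xs - ellipses$x_center[j]) / ellipses$x_semi[j])^2
    qy <- ((ys - ellipses$y_center[j]) / ellipses$y_semi[j])^2
    inside <- inside | outer(qx, qy, "+") <= 1
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Probability mass of an uncorrelated bivariate normal (means mx, my;
# standard deviations sx, sy) inside an axis-aligned ellipse, by
# integrating normal-slice masses over x (no chi-squared identity used).
bvn_ellipse_mass <- function(mx, my, sx, sy, a, b) {
  stats::integrate(
    function(x) {
      half <- b * sqrt(pmax(0, 1 - ((x - mx) / a)^2))
      stats::dnorm(x, mx, sx) *
        (stats::pnorm(my + half, my, sy) - stats::pnorm(my - half, my, sy))
    },
    mx - a, mx + a,
    rel.tol = 1e-10
  )$value
}

# Two-signal straight-line set with irregular sampling, spanning (0,0)
# to (1,1); scaling divisors are (1,1) so scaled == unscaled.
line_signal_set <- function() {
  as_signal_set(dplyr::bind_rows(
    tibble::tibble(signal = "a", x = c(0, 0.1, 0.7, 1), y = c(0, 0.1, 0.7, 1)),
    tibble::tibble(signal = "b", x = seq(0, 1, length.out = 11),
                   y = seq(0, 1, length.out = 11))
  ))
}

# Ensemble of one base curve plus iid bivariate Gaussian perturbation at
# every sampled point, for corridor coverage checks.
perturbed_ensemble <- function(n_signals, noise_sd, seed,
                               n_points = 200) {
  u <- seq(0, 1, length.out = n_points)
  base_x <- u
  base_y <- u^2 * (3 - 2 * u)
  withr::with_seed(seed, {
    dplyr::bind_rows(purrr::map(seq_len(n_signals), function(i) {
      tibble::tibble(
        signal = sprintf("sig_%02d", i),
        x = base_x + stats::rnorm(n_points, sd = noise_sd),
        y = base_y + stats::rnorm(n_points, sd = noise_sd)
      )
    }))
  })
}

# Max over vertices of ring a of the distance to the nearest vertex of
# ring b: a rotation-insensitive measure of closed-polygon agreement.
ring_nn_distance <- function(a, b) {
  max(vapply(seq_len(nrow(a)), function(i) {
    sqrt(min((b$x - a$x[i])^2 + (b$y - a$y[i])^2))
  }, numeric(1)))
}

# Maximum deviation of a warp from the identity on a dense grid.
warp_deviation_grid <- function(w, n = 1001) {
  s <- seq(0, 1, length.out = n)
  max(abs(eval_warp(w, s) - s))
}

# Mean per-grid-point fraction of signal points falling inside their own
# grid point's confidence ellipse.
own_ellipse_coverage <- function(result) {
  ell <- result$ellipses
  reg <- result$registration$registered
  labs <- unique(reg$signal)
  inside <- vapply(labs, function(lab) {
    sig <- reg[reg$signal == lab, ]
    q <- ifelse(
      ell$x_semi == 0 | ell$y_semi == 0, Inf,
      ((sig$x - ell$x_center) / ell$x_semi)^2 +
        ((sig$y - ell$y_center) / ell$y_semi)^2
    )
    q <= 1
  }, logical(nrow(ell)))
  mean(rowMeans(inside))
}
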