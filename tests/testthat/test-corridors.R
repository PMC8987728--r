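test_that("point-wise statistics are per-grid means and sample SDs", {
  s <- seq(0, 1, length.out = 5)
  base <- tibble::tibble(s = s, x = s, y = s^2)
  d <- 0.3
  reg <- dplyr::bind_rows(
    dplyr::mutate(base, signal = "a", y = y + d),
    dplyr::mutate(base, signal = "b", y = y - d)
  )
  st <- pointwise_stats(reg)
  expect_equal(st$x_mean, s)
  expect_equal(st$y_mean, s^2)
  expect_equal(st$x_sd, rep(0, 5))
  expect_equal(st$y_sd, rep(sqrt(2) * d, 5)) # sample SD of {+d, -d}

  # identical signals: zero variance everywhere
  regi <- dplyr::bind_rows(
    dplyr::mutate(base, signal = "a"),
    dplyr::mutate(base, signal = "b"),
    dplyr::mutate(base, signal = "c")
  )
  sti <- pointwise_stats(regi)
  expect_equal(sti$x_sd, rep(0, 5))
  expect_equal(sti$y_sd, rep(0, 5))
})

test_that("sample SD recovers the generating noise level", {
  # signals sampled directly on the common grid: base curve plus iid
  # Gaussian y-noise of known sigma
  sigma <- 0.05
  s <- seq(0, 1, length.out = 100)
  reg <- withr::with_seed(21, {
    dplyr::bind_rows(purrr::map(1:50, function(i) {
      tibble::tibble(
        signal = sprintf("s%02d", i), s = s, x = s,
        y = sin(2 * s) + rnorm(100, sd = sigma)
      )
    }))
  })
  st <- pointwise_stats(reg)
  interior <- st[st$s > 0.1 & st$s < 0.9, ]
  expect_lt(abs(median(interior$y_sd) - sigma) / sigma, 0.2)
  expect_equal(mean(interior$y_sd), sigma, tolerance = 0.1)
})

test_that("the 2-dof chi-squared quantile has its closed form", {
  expect_equal(chi2_quantile_2dof(0), 0)
  expect_equal(chi2_quantile_2dof(0.394), 1, tolerance = 2e-3)
  expect_equal(chi2_quantile_2dof(0.95), -2 * log(0.05))
  expect_equal(chi2_quantile_2dof(0.95), 5.991, tolerance = 1e-4)
  expect_error(chi2_quantile_2dof(1), "p")
  # cross-check against the generic quantile function
  for (p in c(0.1, 0.394, 0.5, 0.9, 0.99)) {
    expect_equal(chi2_quantile_2dof(p), stats::qchisq(p, df = 2))
  }
})

test_that("confidence ellipses scale SDs by the root chi-squared quantile", {
  st <- tibble::tibble(
    s = c(0, 1), x_mean = c(0, 2), y_mean = c(1, 3),
    x_sd = c(1, 1), y_sd = c(1, 0.5)
  )
  # chi2 = 1: a circle of radius equal to the (equal) SDs
  p1 <- 1 - exp(-1 / 2)
  e1 <- confidence_ellipses(st, p = p1)
  expect_equal(e1$x_semi[1], 1)
  expect_equal(e1$y_semi[1], 1)
  # chi2 = 4: semi-axes 2*SD
  p4 <- 1 - exp(-2)
  e4 <- confidence_ellipses(st, p = p4)
  expect_equal(e4$x_semi[2], 2)
  expect_equal(e4$y_semi[2], 1)
  # zero SD: degenerate point axis
  st0 <- tibble::tibble(s = 0, x_mean = 5, y_mean = 5, x_sd = 0, y_sd = 0)
  e0 <- confidence_ellipses(st0, p = 0.95)
  expect_equal(e0$x_semi, 0)
  expect_equal(e0$y_semi, 0)
})

test_that("chi-squared coverage identity matches numeric bivariate mass", {
  # mass inside the ellipse with semi-axes sqrt(q) * SD equals p, checked
  # by slice integration of the density (no chi-squared identity used)
  for (p in c(0.2, 0.394, 0.8)) {
    q <- chi2_quantile_2dof(p)
    mass <- bvn_ellipse_mass(
      mx = 1, my = -2, sx = 0.7, sy = 2.2,
      a = sqrt(q) * 0.7, b = sqrt(q) * 2.2
    )
    expect_equal(mass, p, tolerance = 1e-6)
  }
})

test_that("the envelope of a single circle has the right area", {
  ell <- tibble::tibble(
    s = 0.5, x_center = 1, y_center = -2, x_semi = 2, y_semi = 2
  )
  env <- extract_envelope(ell)
  area <- abs(pracma::polyarea(env$x, env$y))
  expect_lt(abs(area - pi * 4) / (pi * 4), 0.01)
  # closed ring
  expect_equal(env$x[1], env$x[nrow(env)])
  expect_equal(env$y[1], env$y[nrow(env)])
})

test_that("coincident ellipses do not change the envelope", {
  one <- tibble::tibble(
    s = 0.5, x_center = 0, y_center = 0, x_semi = 1.5, y_semi = 0.5
  )
  two <- dplyr::bind_rows(one, one)
  a1 <- abs(pracma::polyarea(extract_envelope(one)$x, extract_envelope(one)$y))
  a2 <- abs(pracma::polyarea(extract_envelope(two)$x, extract_envelope(two)$y))
  expect_equal(a2, a1, tolerance = 1e-6)
})

test_that("envelope area of an overlapping chain matches grid-union oracle", {
  withr::with_seed(31, {
    k <- 20
    cx <- cumsum(runif(k, 0.2, 0.5))
    ell <- tibble::tibble(
      s = seq(0, 1, length.out = k),
      x_center = cx,
      y_center = 0.3 * sin(cx),
      x_semi = runif(k, 0.4, 0.8),
      y_semi = runif(k, 0.4, 0.8)
    )
  })
  env <- extract_envelope(ell)
  area <- abs(pracma::polyarea(env$x, env$y))
  oracle <- grid_union_area(ell, n = 900)
  expect_lt(abs(area - oracle) / oracle, 0.015)
})

test_that("fully degenerate ellipse sets collapse to the average", {
  ell <- tibble::tibble(
    s = c(0, 0.5, 1), x_center = c(0, 1, 2), y_center = c(0, 1, 0),
    x_semi = 0, y_semi = 0
  )
  expect_warning(env <- extract_envelope(ell), "degenerate")
  expect_equal(sort(unique(env$x)), c(0, 1, 2))
})

test_that("densifying an ellipse family preserves ends and connectivity", {
  ell <- tibble::tibble(
    s = seq(0, 1, length.out = 5),
    x_center = seq(0, 4, length.out = 5), y_center = 0,
    x_semi = 0.1, y_semi = 0.1
  )
  dens <- densify_ellipses(ell)
  expect_gt(nrow(dens), nrow(ell))
  expect_equal(dens[1, ], ell[1, ])
  expect_equal(dens[nrow(dens), ], ell[nrow(ell), ])
  # consecutive centers now closer than the overlap requirement
  d <- sqrt(diff(dens$x_center)^2 + diff(dens$y_center)^2)
  expect_lt(max(d), 0.1)
  # already-dense families are untouched
  dense_in <- densify_ellipses(dplyr::mutate(ell, x_semi = 3, y_semi = 3))
  expect_equal(nrow(dense_in), nrow(ell))
})

test_that("a straight corridor splits into two parallel offset polylines", {
  k <- 41
  ell <- tibble::tibble(
    s = seq(0, 1, length.out = k),
    x_center = seq(0, 10, length.out = k), y_center = 0,
    x_semi = 1, y_semi = 1
  )
  avg <- tibble::tibble(x = ell$x_center, y = ell$y_center)
  env <- extract_envelope(ell)
  sides <- split_corridor(env, avg)
  expect_true(sides$split)
  # along the mid-section both corridors run parallel at distance ~1
  for (side in list(sides$inner, sides$outer)) {
    mid <- side[side$x > 2 & side$x < 8, ]
    expect_gt(nrow(mid), 5)
    expect_equal(mean(abs(mid$y)), 1, tolerance = 0.03)
  }
  # opposite signed sides
  expect_lt(
    max(sides$inner$y[sides$inner$x > 2 & sides$inner$x < 8]) *
      max(sides$outer$y[sides$outer$x > 2 & sides$outer$x < 8]),
    0
  )
  # cut endpoints lie near the envelope vertices nearest the average ends
  expect_lt(abs(sides$inner$x[1] - avg$x[1]), 1.1)
  expect_lt(abs(sides$outer$x[1] - avg$x[1]), 1.1)
  # partition: arcs jointly use at least all envelope vertices
  expect_gte(nrow(sides$inner) + nrow(sides$outer) + 2, nrow(env) - 1)
})

test_that("an average outside the envelope is reported, not split", {
  ell <- tibble::tibble(
    s = 0.5, x_center = 0, y_center = 0, x_semi = 1, y_semi = 1
  )
  env <- extract_envelope(ell)
  far <- tibble::tibble(x = c(5, 6), y = c(5, 6))
  expect_warning(out <- split_corridor(env, far), "not enclosed")
  expect_false(out$split)
  expect_equal(out$inner, env)
})
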