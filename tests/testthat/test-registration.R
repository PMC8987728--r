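test_that("pairwise correlation matches the hand-computed Pearson value", {
  a <- c(1, 2, 3, 5)
  b <- c(1, 2, 4, 6)
  # deviations: a - 2.75, b - 3.25; r = 11.25 / sqrt(8.75 * 14.75)
  expect_equal(pairwise_correlation(a, b), 11.25 / sqrt(8.75 * 14.75))
  expect_equal(pairwise_correlation(a, b), 0.9903, tolerance = 1e-4)
  expect_equal(pairwise_correlation(a, a), 1)
  expect_equal(pairwise_correlation(a, -a + 7), -1)
  expect_warning(r0 <- pairwise_correlation(a, rep(2, 4)), "Constant")
  expect_equal(r0, 0)
})

test_that("the ensemble score is the mean off-diagonal correlation", {
  withr::with_seed(4, {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
  })
  sc <- correlation_score(X, Y)
  brute <- function(M) {
    mean(c(
      pairwise_correlation(M[, 1], M[, 2]),
      pairwise_correlation(M[, 1], M[, 3]),
      pairwise_correlation(M[, 2], M[, 3])
    ))
  }
  expect_equal(sc$C_x, brute(X))
  expect_equal(sc$C_y, brute(Y))
  expect_equal(sc$combined, (sc$C_x + sc$C_y) / 2)

  # n identical signals: all off-diagonal correlations are 1
  Xi <- matrix(rep(X[, 1], 4), 10, 4)
  sci <- correlation_score(Xi, Xi)
  expect_equal(sci$combined, 1)

  # n = 2 reduces to the single pairwise correlation
  sc2 <- correlation_score(X[, 1:2], Y[, 1:2])
  expect_equal(sc2$C_x, pairwise_correlation(X[, 1], X[, 2]))
})

test_that("the warp penalty integrates squared deviation from identity", {
  expect_equal(warp_penalty(list(identity_warp(), identity_warp()), 5), 0)
  w <- warp_function(0.3, 0.6)
  expect_equal(warp_penalty(list(w), 0), 0)

  # h(s) ~ s^2 through dense controls: integral of (s^2 - s)^2 is 1/30
  sc <- seq(0.02, 0.98, length.out = 25)
  wq <- warp_function(sc, sc^2)
  expect_equal(
    warp_penalty(list(wq), 1, grid = seq(0, 1, length.out = 500)),
    1 / 30,
    tolerance = 1e-3
  )

  # averaging over signals: one identity halves the single-warp penalty
  expect_equal(
    warp_penalty(list(wq, identity_warp()), 1,
      grid = seq(0, 1, length.out = 500)
    ),
    warp_penalty(list(wq), 1, grid = seq(0, 1, length.out = 500)) / 2
  )
})

test_that("registering identical signals keeps warps at the identity", {
  t <- seq(0, 1, length.out = 150)
  base <- exp(-t) * sin(4 * pi * t)
  set <- as_signal_set(dplyr::bind_rows(
    tibble::tibble(signal = "a", x = t, y = base),
    tibble::tibble(signal = "b", x = t, y = base)
  ))
  rp <- reparameterize(set, n_resample = 100)
  reg <- register_signals(rp, m = 2, lambda = 1e-2)
  for (w in reg$warps) {
    expect_lt(max(abs(eval_warp(w, seq(0, 1, 0.01)) - seq(0, 1, 0.01))), 1e-4)
  }
  expect_equal(reg$score_after, reg$score_before, tolerance = 1e-6)
})

test_that("registration improves the score of a pre-warped signal pair", {
  t <- seq(0, 1, length.out = 300)
  base_fun <- function(s) exp(-1.5 * s) * sin(6 * pi * s)
  prewarp <- function(s) s + 0.1 * sin(2 * pi * s) # known monotone map
  set <- as_signal_set(dplyr::bind_rows(
    tibble::tibble(signal = "orig", x = t, y = base_fun(t)),
    tibble::tibble(signal = "warped", x = t, y = base_fun(prewarp(t)))
  ))
  rp <- reparameterize(set, n_resample = 150)
  reg <- register_signals(rp, m = 3, lambda = 1e-2)
  expect_gte(reg$score_after, reg$score_before - 1e-6)
  expect_gt(reg$score_after, reg$score_before)
  # the correlation itself improves clearly (penalty at identity is zero,
  # so score_before is the identity-warp correlation)
  expect_gt((reg$C_x + reg$C_y) / 2, reg$score_before + 1e-3)

  # mean squared disagreement between the two y traces shrinks
  msd <- function(tbl) {
    ys <- split(tbl$y, tbl$signal)
    mean((ys[[1]] - ys[[2]])^2)
  }
  expect_lt(msd(reg$registered), msd(rp))

  # returned warps are monotone with exact anchors
  for (w in reg$warps) {
    dense <- eval_warp(w, seq(0, 1, length.out = 500))
    expect_true(all(diff(dense) >= 0))
    expect_equal(dense[1], 0)
    expect_equal(dense[500], 1)
  }
})

test_that("m = 0 disables registration entirely", {
  fam <- generate_oscillatory(n_signals = 3, seed = 8)
  rp <- reparameterize(fam$signals, n_resample = 80)
  reg <- register_signals(rp, m = 0)
  expect_equal(reg$registered$x, rp$x)
  expect_equal(reg$registered$y, rp$y)
  expect_equal(reg$score_after, reg$score_before)
  expect_equal(length(reg$warps), 3)
})

test_that("warps converge to the identity as the penalty factor grows", {
  t <- seq(0, 1, length.out = 200)
  set <- as_signal_set(dplyr::bind_rows(purrr::map(1:3, function(i) {
    phi <- c(-0.3, 0, 0.3)[i]
    tibble::tibble(
      signal = paste0("s", i), x = t,
      y = exp(-t) * sin(4 * pi * t + phi)
    )
  })))
  rp <- reparameterize(set, n_resample = 100)
  max_dev <- function(lambda) {
    reg <- register_signals(rp, m = 2, lambda = lambda)
    max(vapply(reg$warps, warp_deviation_grid, numeric(1)))
  }
  devs <- vapply(c(1e-2, 1, 100), max_dev, numeric(1))
  expect_gt(devs[1], devs[2])
  expect_lt(devs[3], 1e-3) # effectively no registration at all
  reg_lo <- register_signals(rp, m = 2, lambda = 1e-2)
  reg_hi <- register_signals(rp, m = 2, lambda = 1)
  corr_lo <- (reg_lo$C_x + reg_lo$C_y) / 2
  corr_hi <- (reg_hi$C_x + reg_hi$C_y) / 2
  expect_gte(corr_lo, corr_hi)
})

test_that("registration tidiers expose control points and scores", {
  fam <- generate_oscillatory(n_signals = 3, seed = 8)
  rp <- reparameterize(fam$signals, n_resample = 80)
  reg <- register_signals(rp, m = 0)
  td <- tidy(reg)
  expect_named(td, c("signal", "control", "s", "h"))
  gl <- glance(reg)
  expect_equal(gl$n_signals, 3)
  expect_equal(gl$m, 0)
})
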