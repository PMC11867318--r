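test_that("gLV right-hand side matches the model equations", {
  p <- glv_params(c(0.5, 0.4, 0.3, 0.5),
                  matrix(c(-0.02, 0.01, 0, -0.01,
                           -0.03, -0.02, 0, 0,
                           0, 0, -0.02, 0.02,
                           -0.01, 0, 0.05, -0.022),
                         4, 4, byrow = TRUE))
  x <- c(2, 1, 0.5, 0.25)
  expect_equal(glv_rhs(x, 0, p),
               as.numeric(x * (p$k_grow + p$alpha %*% x)))
  # extinction is absorbing
  expect_equal(glv_rhs(rep(0, 4), 0, p), rep(0, 4))
  # logistic fixed point of the decoupled probiotic (null-strain values)
  p_null <- glv_params(c(0.5, 0.4, 0.3, 0.5),
                       diag(c(-0.02, -0.02, -0.02, -0.022)))
  d <- glv_rhs(c(0, 0, 0, 0.5 / 0.022), 0, p_null)
  expect_equal(d[4], 0, tolerance = 1e-12)
})

test_that("antibiotic windows substitute the nAB kill rate", {
  p <- glv_params(c(0.5, 0.4, 0.3, 0.5),
                  diag(c(-1e-9, -0.02, -0.02, -0.022)) - 0)
  w <- list(antibiotic_window(0, 7, k_kill = -2.64))
  d_in <- glv_rhs(c(1, 0, 0, 0), 3, p, w)
  expect_equal(d_in[1], -2.64 * 1 + (-1e-9), tolerance = 1e-6)
  d_out <- glv_rhs(c(1, 0, 0, 0), 8, p, w)
  expect_gt(d_out[1], 0)
  # trajectory is first-order decay when self-interaction is negligible
  tr <- simulate_glv(p, c(5, 0, 0, 0), times = c(1, 3, 7), windows = w)
  expect_equal(tr$nAB, 5 * exp(-2.64 * c(1, 3, 7)), tolerance = 1e-4)
  expect_error(glv_rhs(c(1, 0, 0, 0), 1,
                       p, list(antibiotic_window(0, 7), antibiotic_window(5, 9))),
               "overlap")
})

test_that("a stable fixed point is stationary under integration", {
  rp <- resident_params(bistable_draw)
  stable <- stable_fixed_points(rp)
  expect_gt(length(stable), 0)
  params <- community_params(rp, make_strain("null"))
  for (fp in stable) {
    x0 <- c(fp$abundance, P = 0)
    tr <- simulate_glv(params, x0, times = c(50, 100))
    expect_equal(as.numeric(tr[2, 2:5]), as.numeric(x0), tolerance = 1e-6)
  }
})

test_that("a decoupled null probiotic follows its isolated logistic solution", {
  rp <- resident_params(monostable_draw)
  params <- community_params(rp, make_strain("null"))
  init <- c(vapply(stable_fixed_points(rp)[[1]]$abundance, identity, 0), P = 0)
  tt <- c(1, 5, 20, 60)
  tr <- simulate_glv(params, init, times = tt,
                     doses = dose_schedule(0, 2))
  # closed-form logistic with x0 = 2, r = 0.5, K = 0.5/0.022
  K <- 0.5 / 0.022
  logistic <- K / (1 + (K / 2 - 1) * exp(-0.5 * tt))
  expect_equal(tr$P, logistic, tolerance = 1e-6)
})

test_that("dosed simulations match an independent fixed-step RK4 oracle", {
  set.seed(7)
  rp <- resident_params(monostable_draw)
  strain <- make_strain("traditional")
  params <- community_params(rp, strain)
  x0 <- c(10, 1, 1, 0)
  doses <- dose_schedule(0:6, 3)
  tr <- simulate_glv(params, x0, times = 10, doses = doses)
  oracle <- rk4_glv(params$k_grow, params$alpha, x0, t_end = 10,
                    h = 1e-3, doses = doses)
  expect_equal(as.numeric(tr[1, 2:5]), as.numeric(oracle), tolerance = 1e-4)
})

test_that("dosing is conservative when P has no source terms", {
  # k_grow-P = 0 and a zero P row/column: P changes only by the boluses
  p <- glv_params(c(0.5, 0.4, 0.3, 0), diag(c(-0.02, -0.02, -0.02, 0)))
  doses <- dose_schedule(c(0, 1, 2.5, 4), c(1, 2, 0.5, 3))
  tr <- simulate_glv(p, c(5, 1, 1, 0), times = c(3, 10), doses = doses)
  expect_equal(tr$P[1], 3.5, tolerance = 1e-8)
  expect_equal(tr$P[2], sum(doses$amount), tolerance = 1e-8)
})

test_that("solutions are insensitive to tolerance refinement and never negative", {
  rp <- resident_params(bistable_draw)
  params <- community_params(rp, make_strain("bad"))
  x0 <- c(20, 0.5, 0.2, 0)
  reg <- make_regimen("lactin_v", dose_amount = 5)
  a <- simulate_glv(params, x0, times = reg$eval_times, doses = reg$doses,
                    windows = reg$windows)
  b <- simulate_glv(params, x0, times = reg$eval_times, doses = reg$doses,
                    windows = reg$windows, rtol = 5e-7, atol = 5e-10)
  expect_true(all(as.matrix(a[, 2:5]) >= 0))
  rel <- abs(as.matrix(a[, 2:5]) - as.matrix(b[, 2:5])) /
    pmax(as.matrix(b[, 2:5]), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("invalid inputs are rejected", {
  p <- glv_params(c(0.5, 0.4, 0.3, 0.5), diag(rep(-0.02, 4)))
  expect_error(simulate_glv(p, c(-1, 0, 0, 0), times = 1), "negative")
  expect_error(glv_params(c(0.5, 0.4, 0.3, 0.5), diag(c(0.01, -1, -1, -1))),
               "self-interaction")
  expect_error(antibiotic_window(5, 2), "start < end")
  expect_error(antibiotic_window(0, 5, k_kill = 1), "negative")
  expect_error(dose_schedule(1, -2), ">= 0")
})
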