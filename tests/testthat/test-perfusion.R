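test_that("linear system has the stated structure", {
  blood <- plasma_curve(seq(0, 3.2, 0.01), rep(1, 321), tracer = "water")
  fr <- water_frame_schedule()
  # zero tissue: response and tissue-integral column vanish
  z <- tac(fr$start, fr$end, rep(0, nrow(fr)))
  sys0 <- build_linear_system(z, blood)
  expect_true(all(sys0$b == 0))
  expect_true(all(sys0$A[, "neg_int_m"] == 0))
  # constant ca = 1: first column equals the frame mid-times
  expect_equal(unname(sys0$A[, "int_ca"]), (fr$start + fr$end) / 2,
               tolerance = 1e-9)
})

test_that("a noiseless simulated water TAC satisfies the linear relation", {
  blood <- default_water_blood()
  tt <- kinetic_truth(K1 = 0.5, k2 = 0.5 / 0.9, Vo = 0.03)
  sim <- simulate_tissue_tac(blood, tt, water_frame_schedule(), dt = 0.002)
  sys <- build_linear_system(sim, blood)
  x <- c(tt$K1 + tt$k2 * tt$Vo, tt$k2, tt$Vo)
  rel <- sqrt(sum((sys$A %*% x - sys$b)^2)) / sqrt(sum(sys$b^2))
  expect_lt(rel, 1e-2)   # quadrature-limited consistency
})

test_that("nnls_solve projects onto the nonnegative orthant", {
  expect_equal(nnls_solve(diag(2), c(1, -1)), c(1, 0))
  # constraint inactive: equals the unconstrained solution
  set.seed(5)
  A <- matrix(rnorm(30), 10, 3)
  xt <- c(0.5, 1, 2)
  b <- A %*% xt
  expect_equal(nnls_solve(A, b), xt, tolerance = 1e-8)
  expect_error(nnls_solve(matrix(c(1, NA), 1, 2), 1), "non-finite|rows")
})

test_that("nnls_solve matches a brute-force support-enumeration oracle", {
  set.seed(31)
  for (i in 1:50) {
    A <- matrix(rnorm(30), 10, 3)
    b <- rnorm(10)
    x <- nnls_solve(A, b)
    expect_true(all(x >= 0))
    obj <- sum((A %*% x - b)^2)
    expect_equal(obj, nnls_brute_objective(A, b), tolerance = 1e-6)
    # KKT: gradient nonnegative, complementary slackness
    g <- drop(crossprod(A, A %*% x - b))
    expect_true(all(g > -1e-8))
    expect_lt(max(abs(g * x)), 1e-8)
  }
})

test_that("NNLS equals OLS whenever OLS is elementwise nonnegative", {
  set.seed(8)
  found <- 0
  while (found < 10) {
    A <- matrix(abs(rnorm(30)), 10, 3)
    b <- A %*% runif(3, 0.2, 1) + rnorm(10, sd = 0.05)
    ols <- qr.solve(A, b)
    if (all(ols >= 0)) {
      expect_equal(nnls_solve(A, b), drop(ols), tolerance = 1e-8)
      found <- found + 1
    }
  }
})

test_that("noiseless CBF round trip recovers flow within 1% across a truth grid", {
  blood <- default_water_blood()
  fr <- water_frame_schedule()
  for (f in c(0.30, 0.40, 0.54, 0.60)) for (k2 in c(0.4, 0.9)) {
    tt <- kinetic_truth(K1 = f, k2 = k2, Vo = 0.03)
    sim <- simulate_tissue_tac(blood, tt, fr, dt = 0.002)
    fit <- fit_cbf(sim, blood)
    expect_equal(fit$F, 100 * f, tolerance = 0.01)
  }
})

test_that("zero tissue activity gives zero flow, and parameters stay nonnegative", {
  blood <- default_water_blood()
  fr <- water_frame_schedule()
  z <- tac(fr$start, fr$end, rep(0, nrow(fr)))
  fit <- fit_cbf(z, blood)
  expect_equal(fit$F, 0)
  expect_true(all(coef(fit) >= 0))
})

test_that("CBF estimates are scale-equivariant in the activity units", {
  blood <- default_water_blood()
  tt <- kinetic_truth(0.5, 0.6, Vo = 0.03)
  sim <- simulate_tissue_tac(blood, tt, water_frame_schedule(), dt = 0.005)
  f1 <- fit_cbf(sim, blood)
  c <- 3.7
  blood2 <- plasma_curve(blood$times, c * blood$activity, tracer = "water")
  sim2 <- tac(sim$frame_start, sim$frame_end, c * sim$activity)
  f2 <- fit_cbf(sim2, blood2)
  expect_equal(f2$F, f1$F, tolerance = 1e-9)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-9)
  expect_equal(f2$V0, f1$V0, tolerance = 1e-9)
})

test_that("noisy CBF recovery: median error under 5% across 200 replicates", {
  set.seed(404)
  blood <- default_water_blood()
  fr <- water_frame_schedule()
  tt <- kinetic_truth(0.54, 0.6, Vo = 0.03)
  f <- replicate(200, {
    sim <- simulate_tissue_tac(blood, tt, fr, noise_scale = 0.1, dt = 0.005)
    fit_cbf(sim, blood)$F
  })
  expect_lt(median(abs(f - 54) / 54), 0.05)
})
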