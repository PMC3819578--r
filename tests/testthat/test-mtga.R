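test_that("Patlak coordinates obey their closed forms", {
  # constant ca: Theta(T) = T
  pl <- plasma_curve(seq(0, 10, 0.1), rep(2, 101))
  fr <- data.frame(start = 0:9, end = 1:10)
  tt <- tac(fr$start, fr$end, rep(1, 10))
  mv <- mtga_variables(tt, pl)
  expect_equal(mv$theta, frame_mid <- (fr$start + fr$end) / 2, tolerance = 1e-9)
  # pure vascular signal: V(T) = Vo
  tv <- tac(fr$start, fr$end, rep(2 * 0.07, 10))
  expect_equal(mtga_variables(tv, pl)$v, rep(0.07, 10), tolerance = 1e-12)
  # exponential ca: Theta(T) = (exp(lambda T) - 1) / lambda
  lam <- 0.3
  tg <- seq(0, 10, 0.001)
  ple <- plasma_curve(tg, exp(-lam * tg))
  mve <- mtga_variables(tt, ple)
  mid <- (fr$start + fr$end) / 2
  expect_equal(mve$theta, (exp(lam * mid) - 1) / lam, tolerance = 1e-4)
})

test_that("zero plasma activity at a frame mid-time is a named degenerate error", {
  tg <- seq(0, 10, 0.1)
  pl <- plasma_curve(tg, c(rep(1, 51), rep(0, 50)))
  tt <- tac(0:9, 1:10, rep(1, 10))
  expect_error(mtga_variables(tt, pl), "frame [0-9]+")
})

test_that("model equation: reversible form is the K = 0 case of the full form", {
  th <- seq(0, 20, length.out = 400)
  for (p in list(c(0.28, 1, 0.05), c(0.1, 5, 0), c(0.5, 0.2, 0.2))) {
    eq3 <- petbbt:::.mtga_v(th, K = 0, K1 = p[1], Vg = p[2], Vo = p[3])
    eq4 <- p[2] * (1 - exp(-p[1] * th / p[2])) + p[3]
    expect_lt(max(abs(eq3 - eq4)), 1e-12)
    # monotone nondecreasing, bounded by Vg + Vo
    expect_true(all(diff(eq3) >= -1e-14))
    expect_true(all(eq3 <= p[2] + p[3] + 1e-12))
  }
})

test_that("early-time slope of the reversible form equals K1", {
  eps <- 1e-7
  for (K1 in c(0.1, 0.28)) {
    d <- (petbbt:::.mtga_v(eps, 0, K1, 1.3, 0.05) -
            petbbt:::.mtga_v(0, 0, K1, 1.3, 0.05)) / eps
    expect_equal(d, K1, tolerance = 1e-6)
  }
})

test_that("reversible fit reproduces exact constant-input model data", {
  # data generated directly from the constant-input solution, for which the
  # reversible model form is exact
  th <- seq(0.25, 30, by = 0.5)
  v <- 2.5 * (1 - exp(-0.1 * th)) + 0.05   # K1 = 0.25, Vg = 2.5, Vo = 0.05
  mv <- structure(list(theta = th, v = v, mid_times = th,
                       durations = rep(0.5, length(th)), region = "FL"),
                  class = "mtga_vars")
  fit <- fit_mtga(mv, "reversible", window = c(0, 30))
  expect_lt(fit$rss, 1e-10)
  expect_equal(coef(fit)[["K1"]], 0.25, tolerance = 1e-5)
  expect_equal(coef(fit)[["Vg"]], 2.5, tolerance = 1e-4)
  expect_equal(coef(fit)[["Vo"]], 0.05, tolerance = 1e-5)
})

test_that("simulated constant-input data round-trips through the whole chain", {
  pl <- plasma_curve(seq(0, 30, 0.25), rep(1, 121))
  tt <- kinetic_truth(K1 = 0.25, k2 = 0.1, Vo = 0.05)
  sim <- simulate_tissue_tac(pl, tt, data.frame(start = seq(0, 29), end = seq(1, 30)))
  fit <- fit_mtga(mtga_variables(sim, pl), "reversible", window = c(0, 30))
  expect_equal(coef(fit)[["K1"]], 0.25, tolerance = 1e-3)
  expect_equal(coef(fit)[["Vg"]], 2.5, tolerance = 1e-2)
})

test_that("linear fit is exact on a straight line", {
  th <- seq(0, 5, 0.5)
  mv <- structure(list(theta = th, v = 0.28 * th + 0.04, mid_times = th,
                       durations = rep(0.5, length(th)), region = "FL"),
                  class = "mtga_vars")
  fit <- suppressWarnings(fit_mtga(mv, "linear", window = c(0, 5)))
  expect_equal(coef(fit)[["K1"]], 0.28, tolerance = 1e-12)
  expect_equal(coef(fit)[["Vo"]], 0.04, tolerance = 1e-12)
  expect_true(is.infinite(coef(fit)[["Vg"]]))
})

test_that("realistic-AIF noiseless K1 recovery is within 5% in the 0-4 min window", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(12)
  for (K1 in c(0.22, 0.28)) {
    tt <- kinetic_truth(K1 = K1, k2 = K1 / 1.0, Vo = 0.05)
    sim <- simulate_tissue_tac(aif, tt, fr, dt = 0.01, use_parent = TRUE)
    fit <- fit_mtga(mtga_variables(sim, aif), "reversible", window = c(0, 4))
    expect_equal(coef(fit)[["K1"]], K1, tolerance = 0.05)
  }
})

test_that("noisy K1 recovery: median error under 10% across 200 replicates", {
  set.seed(202)
  aif <- default_pib_aif()
  fr <- short_pib_frames(12)
  tt <- kinetic_truth(0.24, 0.24, Vo = 0.05)
  k1 <- replicate(200, {
    sim <- simulate_tissue_tac(aif, tt, fr, noise_scale = 0.1, dt = 0.01,
                               use_parent = TRUE)
    coef(fit_mtga(mtga_variables(sim, aif), "reversible"))[["K1"]]
  })
  expect_lt(median(abs(k1 - 0.24) / 0.24), 0.10)
})

test_that("window semantics use real frame mid-times and reject thin windows", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(12)
  tt <- kinetic_truth(0.24, 0.24, Vo = 0.05)
  mv <- mtga_variables(simulate_tissue_tac(aif, tt, fr, dt = 0.01,
                                           use_parent = TRUE), aif)
  fit <- fit_mtga(mv, "reversible", window = c(0, 4))
  expect_true(all(fit$mid_times <= 4))
  expect_gt(max(mv$theta[mv$mid_times <= 4]), 4)  # Theta runs ahead of real time
  expect_error(fit_mtga(mv, "reversible", window = c(0, 0.2)),
               "insufficient")
})

test_that("all-zero tissue signal yields the zero-parameter fit", {
  th <- seq(0.25, 10, 0.5)
  mv <- structure(list(theta = th, v = rep(0, length(th)), mid_times = th,
                       durations = rep(0.5, length(th)), region = "FL"),
                  class = "mtga_vars")
  fit <- fit_mtga(mv, "reversible", window = c(0, 10))
  expect_equal(unname(coef(fit)), rep(0, 4))
  expect_equal(fit$rss, 0)
})

test_that("select_model applies the 2-SE rule on K", {
  mk <- function(K, seK) {
    structure(list(model = "full",
                   coefficients = c(K = K, K1 = 0.3, Vg = 1, Vo = 0.05),
                   se = c(K = seK, K1 = 0.01, Vg = 0.1, Vo = 0.01)),
              class = "mtga_fit")
  }
  expect_identical(select_model(mk(0.001, 0.01)), "reversible")
  expect_identical(select_model(mk(0.05, 0.01)), "full")
  expect_error(select_model(mk(0.05, NA_real_)), "SE")
})

test_that("a real trapping component is detected in most low-noise replicates", {
  # constant input: the irreversible model form is exact, so the K decision
  # reflects estimation noise only
  set.seed(11)
  pl <- plasma_curve(seq(0, 30, 0.25), rep(1, 121))
  fr <- data.frame(start = seq(0, 29), end = seq(1, 30))
  tt <- kinetic_truth(K1 = 0.25, k2 = 0.1, Vo = 0.05, K = 0.02)
  sel <- replicate(100, {
    sim <- simulate_tissue_tac(pl, tt, fr, noise_scale = 0.01, dt = 0.01)
    select_model(fit_mtga(mtga_variables(sim, pl), "full", window = c(0, 30)))
  })
  expect_gt(mean(sel == "full"), 0.8)
})

test_that("patlak_plot_data evaluates the fitted model at the observed Theta", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(12)
  tt <- kinetic_truth(0.24, 0.24, Vo = 0.05)
  mv <- mtga_variables(simulate_tissue_tac(aif, tt, fr, dt = 0.01,
                                           use_parent = TRUE), aif)
  fit <- fit_mtga(mv, "reversible")
  pd <- patlak_plot_data(mv, fit)
  expect_identical(pd$theta, mv$theta)
  expect_equal(predict(fit, list(theta = 0)), coef(fit)[["Vo"]])
  # Vg -> infinity limit approaches the straight line K1 Theta + Vo
  th <- seq(0.01, 4, length.out = 100)
  curve_big <- petbbt:::.mtga_v(th, 0, 0.28, 1e6, 0.04)
  line <- 0.28 * th + 0.04
  expect_lt(max(abs(curve_big - line) / line), 1e-3)
})
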