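test_that("zero kinetics give an all-zero TAC", {
  pl <- plasma_curve(seq(0, 10, 0.5), rep(1, 21))
  tt <- kinetic_truth(K1 = 0, k2 = 0.1, Vo = 0)
  sim <- simulate_tissue_tac(pl, tt, data.frame(start = 0:9, end = 1:10))
  expect_true(all(sim$activity == 0))
})

test_that("constant-input TAC matches the closed-form convolution", {
  # ca = 1 everywhere: M(t) = (K1/k2) (1 - exp(-k2 t)) + Vo, and the frame
  # value is its exact average over the frame
  pl <- plasma_curve(seq(0, 30, 0.5), rep(1, 61))
  fr <- data.frame(start = seq(0, 29), end = seq(1, 30))
  for (vo in c(0, 0.05)) {
    tt <- kinetic_truth(K1 = 0.25, k2 = 0.1, Vo = vo)
    sim <- simulate_tissue_tac(pl, tt, fr)
    a <- fr$start; b <- fr$end
    avg <- 2.5 * (1 - (exp(-0.1 * a) - exp(-0.1 * b)) / (0.1 * (b - a))) + vo
    expect_equal(sim$activity, avg, tolerance = 1e-6)
  }
})

test_that("noiseless tissue signal is linear in K1", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(10)
  s1 <- simulate_tissue_tac(aif, kinetic_truth(0.1, 0.1, Vo = 0), fr)
  s2 <- simulate_tissue_tac(aif, kinetic_truth(0.2, 0.1, Vo = 0), fr)
  expect_equal(s2$activity, 2 * s1$activity, tolerance = 1e-12)
})

test_that("seeded noisy simulations are bit-reproducible and leave the RNG alone", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(10)
  tt <- kinetic_truth(0.25, 0.25, Vo = 0.05)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- simulate_tissue_tac(aif, tt, fr, noise_scale = 0.1, seed = 77)
  after <- runif(1)
  b <- simulate_tissue_tac(aif, tt, fr, noise_scale = 0.1, seed = 77)
  expect_identical(a$activity, b$activity)
  expect_identical(before, after)  # caller RNG stream undisturbed
  c2 <- simulate_tissue_tac(aif, tt, fr, noise_scale = 0.1, seed = 78)
  expect_false(identical(a$activity, c2$activity))
})

test_that("frame schedules beyond the input span are rejected", {
  aif <- default_pib_aif(times = seq(0, 5, 0.1))
  tt <- kinetic_truth(0.25, 0.25)
  expect_error(
    simulate_tissue_tac(aif, tt, data.frame(start = 0, end = 10)),
    "exceeds")
})

test_that("parent-driven kinetics reduce late uptake but keep the vascular term total", {
  aif <- default_pib_aif()
  fr <- short_pib_frames(12)
  tt <- kinetic_truth(0.25, 0.25, Vo = 0)
  tot <- simulate_tissue_tac(aif, tt, fr)
  par <- simulate_tissue_tac(aif, tt, fr, use_parent = TRUE)
  expect_true(all(par$activity <= tot$activity + 1e-12))
  expect_lt(par$activity[nrow(fr)], tot$activity[nrow(fr)])
  # pure vascular signal is insensitive to the driver choice
  tv <- kinetic_truth(0, 0.1, Vo = 0.05)
  expect_equal(simulate_tissue_tac(aif, tv, fr, use_parent = TRUE)$activity,
               simulate_tissue_tac(aif, tv, fr)$activity)
})

test_that("TAC frame validation catches malformed schedules", {
  expect_error(tac(c(0, 1), c(1, 0.5), c(1, 1)), "exceed")
  expect_error(tac(c(0, 0.5), c(1, 1.5), c(1, 1)), "overlap")
})
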