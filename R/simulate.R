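#' Arterial input function shape parameters
#'
#' The synthetic AIF is a gamma-variate bolus plus a saturating plateau,
#' `A (t/tp)^a exp(a (1 - t/tp)) + f A (1 - exp(-t/tau))`, where `A` is the
#' bolus peak amplitude, `tp` the peak time, `a` the bolus sharpness, `f` the
#' plateau fraction and `tau` the plateau onset time constant. The defaults
#' reproduce the triphasic shape typical of a [11C]PiB injection: a sharp
#' peak within the first minute, an immediate decline, and from about 4 min
#' a plateau held near 10% of the peak that is dominated by labeled
#' metabolites, reached at about 4 min.
#'
#' @param peak_time Bolus peak time `tp`, minutes (< 1 min for a realistic
#'   bolus).
#' @param peak_amplitude Bolus peak amplitude `A`, kBq/mL.
#' @param bolus_sharpness Gamma-variate shape `a`, unitless.
#' @param plateau_fraction Plateau level as a fraction of the bolus peak,
#'   in \[0, 1).
#' @param plateau_onset Plateau time constant `tau`, minutes.
#' @return An object of class `aif_shape`.
#' @export
aif_shape <- function(peak_time = 0.5, peak_amplitude = 100,
                      bolus_sharpness = 1.5, plateau_fraction = 0.10,
                      plateau_onset = 1.5) {
  stopifnot(peak_time > 0, peak_amplitude >= 0, bolus_sharpness > 0,
            plateau_fraction >= 0, plateau_fraction < 1, plateau_onset > 0)
  structure(list(peak_time = peak_time, peak_amplitude = peak_amplitude,
                 bolus_sharpness = bolus_sharpness,
                 plateau_fraction = plateau_fraction,
                 plateau_onset = plateau_onset),
            class = "aif_shape")
}

.aif_value <- function(shape, t) {
  tp <- shape$peak_time; a <- shape$bolus_sharpness
  A <- shape$peak_amplitude
  P <- shape$plateau_fraction * A
  bolus <- ifelse(t > 0, A * (t / tp)^a * exp(a * (1 - t / tp)), 0)
  plateau <- ifelse(t > 0, P * (1 - exp(-t / shape$plateau_onset)), 0)
  bolus + plateau
}

#' Simulate an arterial input function
#'
#' Evaluates the gamma-variate-plus-plateau model of [aif_shape()] on a
#' sampling grid. With the defaults, the curve peaks before 1 min and settles
#' at about 10% of the peak from 4 min onward.
#'
#' @param shape An [aif_shape()].
#' @param times Sample times in minutes, strictly increasing.
#' @param parent_params Optional [parent_fraction_params()]; when supplied the
#'   returned curve carries the matching parent-fraction samples.
#' @param tracer Tracer label for the returned curve.
#' @return A [plasma_curve()].
#' @examples
#' aif <- simulate_aif(aif_shape(), seq(0, 90, by = 0.1))
#' @export
simulate_aif <- function(shape = aif_shape(), times = seq(0, 90, by = 0.05),
                         parent_params = NULL, tracer = "PiB") {
  if (length(times) < 2L || any(diff(times) <= 0))
    .stopf("times must be strictly increasing")
  if (any(times < 0)) .stopf("times must be nonnegative")
  act <- .aif_value(shape, times)
  pf <- if (!is.null(parent_params))
    parent_fraction_curve(times, parent_params) else NULL
  plasma_curve(times, act, pf, tracer = tracer)
}

#' Closed-form area under the synthetic AIF
#'
#' Analytic integral of the generating function of [simulate_aif()] over
#' `[0, t_hi]`: the gamma-variate term integrates to an incomplete gamma
#' function and the plateau term has an elementary antiderivative. Used to
#' validate numerical quadrature of simulated curves.
#'
#' @param shape An [aif_shape()].
#' @param t_hi Upper limit in minutes.
#' @return Area in kBq min/mL.
#' @export
aif_auc <- function(shape, t_hi) {
  stopifnot(t_hi >= 0)
  tp <- shape$peak_time; a <- shape$bolus_sharpness
  A <- shape$peak_amplitude
  P <- shape$plateau_fraction * A
  tau <- shape$plateau_onset
  bolus <- A * exp(a) * tp * a^(-(a + 1)) * gamma(a + 1) *
    stats::pgamma(a * t_hi / tp, shape = a + 1)
  plateau <- P * (t_hi - tau * (1 - exp(-t_hi / tau)))
  bolus + plateau
}

#' Parent-fraction model parameters
#'
#' The fraction of plasma activity that is unmetabolized tracer is modelled
#' with a Hill-type decay `f(t) = 1 / (1 + (t / half_time)^hill_exponent)`.
#' The defaults (`half_time` 6 min, exponent 2.4) are calibrated so that,
#' applied to the default AIF, the metabolite-corrected plasma activity
#' falls below 3% of the peak by 10 min and to about 1% by 15 min.
#'
#' @param half_time Time at which the parent fraction reaches 0.5, minutes.
#' @param hill_exponent Hill steepness, unitless, > 0.
#' @return An object of class `parent_fraction_params`.
#' @export
parent_fraction_params <- function(half_time = 6, hill_exponent = 2.4) {
  stopifnot(half_time > 0, hill_exponent > 0)
  structure(list(half_time = half_time, hill_exponent = hill_exponent),
            class = "parent_fraction_params")
}

#' Parent fraction as a function of time
#'
#' @param times Times in minutes, nonnegative.
#' @param params A [parent_fraction_params()].
#' @return Fractions in \[0, 1\], equal to 1 at `t = 0` and nonincreasing.
#' @examples
#' parent_fraction_curve(c(0, 6, 15), parent_fraction_params())
#' @export
parent_fraction_curve <- function(times, params = parent_fraction_params()) {
  times <- as.numeric(times)
  if (any(times < 0)) .stopf("times must be nonnegative")
  1 / (1 + (times / params$half_time)^params$hill_exponent)
}

#' One-tissue kinetic ground truth
#'
#' Parameters of the one-tissue compartment model with a vascular term:
#' unidirectional clearance `K1` (mL g^-1 min^-1), tissue efflux rate `k2`
#' (min^-1), vascular volume `Vo` (mL/cm^3) and, for the irreversible
#' variant, a net trapping clearance `K` (mL g^-1 min^-1; 0 for purely
#' reversible kinetics).
#'
#' @param K1,k2,Vo,K Model parameters, all nonnegative; `k2 > 0` whenever
#'   `K1 > 0` and `K = 0`.
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(K1, k2, Vo = 0, K = 0) {
  stopifnot(K1 >= 0, k2 >= 0, Vo >= 0, K >= 0)
  if (K1 > 0 && K == 0 && k2 <= 0)
    .stopf("k2 must be positive when K1 > 0 and K = 0")
  structure(list(K1 = K1, k2 = k2, Vo = Vo, K = K), class = "kinetic_truth")
}

# Instantaneous model signal M(t) on a uniform grid, computed with an exact
# exponential integrator for piecewise-linear input (exact when ca is linear
# between grid points). The exchange terms (K1, K) are driven by `ca_drive`
# (the parent input when metabolite correction applies); the vascular term
# always carries the total measured blood activity. Returns list(grid, M, ca).
.tissue_signal_grid <- function(aif, truth, t_max, dt, use_parent = FALSE) {
  grid <- seq(0, t_max, by = dt)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  ca_total <- .interp(aif$times, aif$activity, grid)
  ca <- if (use_parent)
    ca_total * .interp(aif$times, aif$parent_fraction, grid) else ca_total
  h <- diff(grid)
  k2 <- truth$k2
  c0 <- ca[-length(ca)]; c1 <- ca[-1L]
  if (truth$K1 > 0) {
    if (k2 > 0) {
      E <- exp(-k2 * h)
      # int_0^h ca(t_n + s) e^{-k2 (h - s)} ds for linear ca
      u <- truth$K1 * (c0 * (1 - E) / k2 +
                         (c1 - c0) * (1 / k2 - (1 - E) / (h * k2^2)))
    } else {
      E <- rep(1, length(h))
      u <- truth$K1 * h * (c0 + c1) / 2
    }
    if (all(abs(h - h[1L]) < 1e-12)) {
      C <- c(0, as.numeric(stats::filter(u, E[1L], method = "recursive")))
    } else {
      C <- numeric(length(grid))
      for (i in seq_along(h)) C[i + 1L] <- C[i] * E[i] + u[i]
    }
  } else {
    C <- numeric(length(grid))
  }
  M <- C + truth$Vo * ca_total
  if (truth$K > 0) M <- M + truth$K * pracma::cumtrapz(grid, ca)[, 1L]
  list(grid = grid, M = M, ca = ca_total)
}

#' Simulate a regional time-activity curve
#'
#' Generates the frame-averaged tissue signal of the one-tissue compartment
#' model driven by an arterial input curve:
#' `M(t) = K1 int_0^t ca(s) exp(-k2 (t - s)) ds + Vo ca(t)`, plus
#' `K int_0^t ca(s) ds` when a net trapping clearance is specified. The
#' convolution is evaluated with an exact exponential integrator on a fine
#' uniform grid (the input is taken piecewise-linear between plasma samples),
#' and each frame value is the time-average of `M` over the frame. Optional
#' noise is zero-mean Gaussian with standard deviation
#' `noise_scale * sqrt(M / frame_duration)`, mimicking count statistics.
#'
#' @param aif A [plasma_curve()] covering the frame schedule's span.
#' @param truth A [kinetic_truth()].
#' @param frames A data frame with columns `start` and `end` (minutes), e.g.
#'   from [water_frame_schedule()] or [pib_frame_schedule()].
#' @param noise_scale Unitless noise magnitude; 0 for a noiseless curve.
#' @param seed Optional integer seed; seeded runs are bit-reproducible and do
#'   not disturb the caller's RNG state.
#' @param region Region label for the returned curve.
#' @param dt Internal integration step, minutes.
#' @param use_parent If `TRUE`, drive the tissue with the metabolite-corrected
#'   (parent) activity, `ca * parent_fraction`: labeled metabolites circulate
#'   but do not cross the blood-brain barrier. Requires a parent fraction on
#'   `aif`.
#' @return A [tac()].
#' @examples
#' aif <- simulate_aif(aif_shape(), seq(0, 10, by = 0.05))
#' tt <- kinetic_truth(K1 = 0.25, k2 = 0.55, Vo = 0.05)
#' simulate_tissue_tac(aif, tt, data.frame(start = 0:9, end = 1:10))
#' @export
simulate_tissue_tac <- function(aif, truth, frames, noise_scale = 0,
                                seed = NULL, region = "CTX", dt = 0.002,
                                use_parent = FALSE) {
  stopifnot(inherits(aif, "plasma_curve"), inherits(truth, "kinetic_truth"))
  if (use_parent && is.null(aif$parent_fraction))
    .stopf("use_parent requires a parent fraction on the input curve")
  frames <- as.data.frame(frames)
  if (!all(c("start", "end") %in% names(frames)))
    .stopf("frames must have columns 'start' and 'end'")
  if (max(frames$end) > max(aif$times) + 1e-9)
    .stopf("frame schedule (to %.2f min) exceeds the AIF span (%.2f min)",
           max(frames$end), max(aif$times))
  sig <- .tissue_signal_grid(aif, truth, max(frames$end), dt, use_parent)
  # cumulative integral of M, interpolated at frame boundaries
  cum <- pracma::cumtrapz(sig$grid, sig$M)[, 1L]
  lo <- .interp(sig$grid, cum, frames$start)
  hi <- .interp(sig$grid, cum, frames$end)
  dur <- frames$end - frames$start
  mbar <- (hi - lo) / dur
  if (noise_scale > 0) {
    mbar <- .with_seed(seed, {
      mbar + stats::rnorm(length(mbar),
                          sd = noise_scale * sqrt(pmax(mbar, 0) / dur))
    })
  }
  tac(frames$start, frames$end, mbar, region = region)
}

#' Dynamic session frame schedules
#'
#' `water_frame_schedule()` is a 3-min, 21-frame session with equal frames;
#' `pib_frame_schedule()` is a 90-min, 30-frame session with a graded
#' schedule (6 x 10 s, 6 x 20 s, 6 x 60 s, 6 x 300 s, 6 x 510 s) whose short
#' early frames capture the bolus passage.
#'
#' @return A data frame with columns `start` and `end` in minutes.
#' @export
water_frame_schedule <- function() {
  b <- seq(0, 3, length.out = 22L)
  data.frame(start = b[-22L], end = b[-1L])
}

#' @rdname water_frame_schedule
#' @export
pib_frame_schedule <- function() {
  dur_s <- rep(c(10, 20, 60, 300, 510), each = 6L)
  b <- c(0, cumsum(dur_s)) / 60
  data.frame(start = b[-31L], end = b[-1L])
}
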