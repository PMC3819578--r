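#' Linearized one-tissue model design matrix
#'
#' Builds the linear system of the linearized one-tissue (two-compartment)
#' water model. Integrating the model
#' `dM/dt = K1 ca - k2 (M - V0 ca)` and folding the vascular term into the
#' measured signal gives, at each frame mid-time `T`,
#' `M(T) = p1 int_0^T ca dt - p2 int_0^T M dt + p3 ca(T)` with
#' `(p1, p2, p3) = (K1 + k2 V0, k2, V0)`, so that `F = K1 = p1 - p2 p3`.
#' Rows are frames; the minus sign is folded into the second column so that
#' a nonnegativity constraint on the solution applies to `k2` directly.
#'
#' The blood integral is trapezoidal on the blood sampling grid; the tissue
#' integral uses the frame averages exactly (the integral over a frame is
#' the frame value times its duration).
#'
#' @param tac A [tac()] of the water session.
#' @param blood A [plasma_curve()] (arterial whole blood) covering the TAC
#'   span.
#' @return A list with the design matrix `A` (columns `int_ca`, `neg_int_m`,
#'   `ca`), response `b` (frame activity) and `mid_times`.
#' @export
build_linear_system <- function(tac, blood) {
  stopifnot(inherits(tac, "tac"), inherits(blood, "plasma_curve"))
  if (max(tac$frame_end) > max(blood$times) + 1e-9)
    .stopf("blood curve does not cover the TAC span")
  mids <- frame_mid(tac)
  dur <- frame_dur(tac)
  cum_ca <- pracma::cumtrapz(blood$times, blood$activity)[, 1L]
  ca_mid <- .interp(blood$times, blood$activity, mids)
  int_ca <- .interp(blood$times, cum_ca, mids)
  # int_0^mid M dt: exact to frame ends from the frame averages, plus half
  # the current frame to reach the mid-time
  cum_m_end <- cumsum(tac$activity * dur)
  int_m <- c(0, cum_m_end[-length(cum_m_end)]) + tac$activity * dur / 2
  A <- cbind(int_ca = int_ca, neg_int_m = -int_m, ca = ca_mid)
  list(A = A, b = tac$activity, mid_times = mids)
}

#' Non-negative least squares
#'
#' Solves `argmin || A x - b ||_2` subject to `x >= 0` with the
#' Lawson-Hanson active-set algorithm.
#'
#' @param A Numeric matrix with at least as many rows as columns.
#' @param b Numeric response vector.
#' @return The nonnegative coefficient vector.
#' @examples
#' nnls_solve(diag(2), c(1, -1))  # c(1, 0)
#' @export
nnls_solve <- function(A, b) {
  A <- as.matrix(A)
  .check_finite(A, "A")
  .check_finite(b, "b")
  if (nrow(A) < ncol(A))
    .stopf("A must have at least as many rows (%d) as columns (%d)",
           nrow(A), ncol(A))
  as.numeric(pracma::lsqnonneg(A, as.numeric(b))$x)
}

#' Estimate regional cerebral blood flow from a water session
#'
#' Fits the linearized one-tissue model of [build_linear_system()] to a
#' 3-min [15O]water session by non-negative least squares and identifies the
#' cerebral blood flow `F` with the water clearance `K1`. Flow is reported
#' in mL hg^-1 min^-1 (100 x the internal mL g^-1 min^-1, with tissue
#' density taken as 1 g/cm^3).
#'
#' @param tac A [tac()] of the water session.
#' @param blood A [plasma_curve()] of arterial blood activity.
#' @param window Analysis window `[t_lo, t_hi]` in minutes applied to frame
#'   mid-times; default the full 0-3 min session.
#' @param include_v0 Include the vascular-volume column (default `TRUE`).
#' @return An object of class `cbf_fit` with components `F` (mL hg^-1
#'   min^-1), `k2` (min^-1), `V0` (mL/cm^3), `residual_norm`, `n_frames`,
#'   `region` and `coefficients` (the raw NNLS solution).
#' @examples
#' aif <- simulate_aif(aif_shape(peak_time = 0.4), seq(0, 3.2, by = 0.01),
#'                     tracer = "water")
#' tt <- kinetic_truth(K1 = 0.5, k2 = 0.55, Vo = 0.03)
#' wt <- simulate_tissue_tac(aif, tt, water_frame_schedule())
#' fit_cbf(wt, aif)
#' @export
fit_cbf <- function(tac, blood, window = c(0, 3), include_v0 = TRUE) {
  stopifnot(inherits(tac, "tac"))
  if (length(window) != 2L || window[2L] <= window[1L])
    .stopf("window must be an increasing [t_lo, t_hi] pair")
  keep <- which(frame_mid(tac) >= window[1L] & frame_mid(tac) <= window[2L])
  npar <- if (include_v0) 3L else 2L
  if (length(keep) < npar + 1L)
    .stopf("insufficient data: %d frames in window", length(keep))
  sub <- tac(tac$frame_start[keep], tac$frame_end[keep], tac$activity[keep],
             region = tac$region)
  sys <- build_linear_system(sub, blood)
  A <- sys$A
  if (!include_v0) A <- A[, 1:2, drop = FALSE]
  x <- nnls_solve(A, sys$b)
  k2 <- x[2L]
  V0 <- if (include_v0) x[3L] else 0
  K1 <- max(x[1L] - k2 * V0, 0)
  structure(list(F = 100 * K1, k2 = k2, V0 = V0,
                 residual_norm = sqrt(sum((A %*% x - sys$b)^2)),
                 n_frames = length(keep), region = tac$region,
                 coefficients = x, window = window),
            class = "cbf_fit")
}

#' @export
print.cbf_fit <- function(x, digits = 4, ...) {
  cat(sprintf("CBF fit, region %s (%d frames, window %g-%g min)\n",
              x$region, x$n_frames, x$window[1L], x$window[2L]))
  cat(sprintf("  F = %s mL/hg/min, k2 = %s /min, V0 = %s mL/cm^3, ||r|| = %.3g\n",
              format(x$F, digits = digits), format(x$k2, digits = digits),
              format(x$V0, digits = digits), x$residual_norm))
  invisible(x)
}

#' @export
coef.cbf_fit <- function(object, ...) {
  c(F = object$F, k2 = object$k2, V0 = object$V0)
}
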