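#' Gjedde-Patlak plot coordinates
#'
#' Transforms a regional time-activity curve and an arterial input curve into
#' the multitime graphical analysis (MTGA) variables: the apparent
#' distribution volume `V(T) = m(T) / ca(T)` (mL/cm^3) and the normalized
#' time `Theta(T) = int_0^T ca(t) dt / ca(T)` (minutes). The plasma integral
#' is computed by the trapezoid rule on the plasma sampling grid; `ca` and
#' its cumulative integral are interpolated linearly to the frame mid-times.
#'
#' @param tac A [tac()].
#' @param plasma A [plasma_curve()] covering the TAC's span with
#'   `ca(T) > 0` at every frame mid-time.
#' @param parent_correction If `TRUE`, multiply the plasma activity by its
#'   parent fraction (which must be present) before forming the variables,
#'   i.e. use the metabolite-corrected input.
#' @return An object of class `mtga_vars`: a list with `theta`, `v`,
#'   `mid_times`, `durations` and `region`.
#' @examples
#' pl <- plasma_curve(seq(0, 10, 0.1), rep(2, 101))
#' tt <- tac(0:9, 1:10, rep(2 * 0.05, 10))  # pure vascular signal, Vo = 0.05
#' mv <- mtga_variables(tt, pl)
#' all.equal(mv$v, rep(0.05, 10))
#' @export
mtga_variables <- function(tac, plasma, parent_correction = FALSE) {
  stopifnot(inherits(tac, "tac"), inherits(plasma, "plasma_curve"))
  ca <- plasma$activity
  if (parent_correction) {
    if (is.null(plasma$parent_fraction))
      .stopf("parent_correction requires a parent fraction on the plasma curve")
    ca <- ca * plasma$parent_fraction
  }
  if (max(tac$frame_end) > max(plasma$times) + 1e-9)
    .stopf("plasma curve does not cover the TAC span")
  mids <- frame_mid(tac)
  cum <- pracma::cumtrapz(plasma$times, ca)[, 1L]
  ca_mid <- .interp(plasma$times, ca, mids)
  cum_mid <- .interp(plasma$times, cum, mids)
  bad <- which(ca_mid <= 0)
  if (length(bad))
    .stopf("plasma activity is zero at the mid-time of frame %d (%.2f min)",
           bad[1L], mids[bad[1L]])
  structure(list(theta = cum_mid / ca_mid, v = tac$activity / ca_mid,
                 mid_times = mids, durations = frame_dur(tac),
                 region = tac$region),
            class = "mtga_vars")
}

#' @export
print.mtga_vars <- function(x, ...) {
  cat(sprintf("<mtga_vars> region %s, %d frames, Theta up to %.2f min\n",
              x$region, length(x$theta), max(x$theta)))
  invisible(x)
}

# Model equation for the irreversible three-compartment MTGA form:
# V = K Theta + Vg (1 - exp(-(K1 - K) Theta / Vg)) + Vo,
# with guards for the degenerate (Vg = 0, K1 = K) and linear (Vg = Inf)
# limits. K = 0 gives the reversible one-tissue form.
.mtga_v <- function(theta, K, K1, Vg, Vo) {
  slope <- K1 - K
  pool <- if (!is.finite(Vg)) {
    slope * theta
  } else if (Vg <= 0 || slope <= 0) {
    rep(0, length(theta))
  } else {
    Vg * (1 - exp(-slope * theta / Vg))
  }
  K * theta + pool + Vo
}

.model_npar <- c(full = 4L, reversible = 3L, linear = 2L)

#' Fit an MTGA model to Patlak-plot coordinates
#'
#' Estimates kinetic parameters from the `(Theta, V)` coordinates of
#' [mtga_variables()] by regression of one of three nested model forms:
#'
#' * `"full"` — `V = K Theta + Vg (1 - exp(-(K1 - K) Theta / Vg)) + Vo`,
#'   the irreversible three-compartment form with net clearance `K`;
#' * `"reversible"` — the same with `K = 0`: a single reversible tissue
#'   compartment, `V = Vg (1 - exp(-K1 Theta / Vg)) + Vo`;
#' * `"linear"` — the early-time limit `V = K1 Theta + Vo`, fit by ordinary
#'   linear regression.
#'
#' The nonlinear forms are fit by bounded Levenberg-Marquardt least squares
#' (parameters bounded below at 0), with start values from a linear fit over
#' the earliest minute and up to three jittered restarts on failure.
#' Analysis is restricted to frames whose mid-times (real minutes, not
#' normalized time) fall inside `window`; the default 0-4 min window
#' confines the fit to the period before labeled metabolites corrupt the
#' plasma input.
#'
#' @param vars An [mtga_vars()] object.
#' @param model `"reversible"` (default), `"full"` or `"linear"`.
#' @param window Closed interval `[t_lo, t_hi]` of real frame mid-times,
#'   minutes.
#' @param weights `"uniform"` (default) or `"frame_duration"` regression
#'   weights.
#' @return An object of class `mtga_fit` with components `coefficients`
#'   (named `K`, `K1`, `Vg`, `Vo`; `K = 0` for the reversible form and
#'   `Vg = Inf` for the linear form), `se`, `model`, `window`, `theta`, `v`,
#'   `fitted`, `residuals`, `rss`, `n` and `converged`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `plot()`, `residuals()` and
#'   `fitted()`.
#' @examples
#' th <- seq(0.1, 8, length.out = 12)
#' mv <- structure(list(theta = th, v = 0.28 * th + 0.04,
#'                      mid_times = seq(0.1, 3.9, length.out = 12),
#'                      durations = rep(0.3, 12), region = "FL"),
#'                 class = "mtga_vars")
#' coef(fit_mtga(mv, model = "linear"))
#' @export
fit_mtga <- function(vars, model = c("reversible", "full", "linear"),
                     window = c(0, 4),
                     weights = c("uniform", "frame_duration")) {
  stopifnot(inherits(vars, "mtga_vars"))
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (length(window) != 2L || window[2L] <= window[1L])
    .stopf("window must be an increasing [t_lo, t_hi] pair")
  idx <- which(vars$mid_times >= window[1L] & vars$mid_times <= window[2L])
  npar <- .model_npar[[model]]
  if (length(idx) < npar + 1L)
    .stopf("insufficient data: %d frames in window [%g, %g], need >= %d",
           length(idx), window[1L], window[2L], npar + 1L)
  th <- vars$theta[idx]; v <- vars$v[idx]
  w <- if (weights == "frame_duration") vars$durations[idx] else rep(1, length(idx))

  res <- if (model == "linear") .fit_mtga_linear(th, v, w)
         else .fit_mtga_nls(th, v, w, vars, idx, window, model)
  structure(c(res,
              list(model = model, window = window, weights = weights,
                   theta = th, v = v, mid_times = vars$mid_times[idx],
                   region = vars$region, n = length(idx))),
            class = "mtga_fit")
}

.fit_mtga_linear <- function(th, v, w) {
  fit <- stats::lm(v ~ th, weights = w)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  coefficients <- c(K = 0, K1 = unname(cf[2L]), Vg = Inf, Vo = unname(cf[1L]))
  fitted <- unname(stats::fitted(fit))
  list(coefficients = coefficients,
       se = c(K = NA_real_, K1 = unname(se[2L]), Vg = NA_real_,
              Vo = unname(se[1L])),
       fitted = fitted, residuals = v - fitted,
       rss = sum(w * (v - fitted)^2), converged = TRUE)
}

# Start values: linear fit over the earliest minute of real time (or the
# first npar+1 frames if fewer fall there); Vg starts at 2 max(V).
.mtga_start <- function(th, v, mids) {
  early <- which(mids <= min(mids) + 1)
  if (length(early) < 3L) early <- seq_len(min(3L, length(th)))
  sl <- stats::coef(stats::lm(v[early] ~ th[early]))
  K1_0 <- max(unname(sl[2L]), 1e-3)
  Vo_0 <- max(unname(sl[1L]), 0)
  c(K1 = K1_0, Vg = max(2 * max(v), 1e-2), Vo = Vo_0)
}

.fit_mtga_nls <- function(th, v, w, vars, idx, window, model) {
  st <- .mtga_start(th, v, vars$mid_times[idx])
  if (max(abs(v)) < 1e-12) {           # degenerate all-zero signal
    z <- c(K = 0, K1 = 0, Vg = 0, Vo = 0)
    return(list(coefficients = z, se = z * NA_real_,
                fitted = rep(0, length(v)), residuals = v,
                rss = sum(w * v^2), converged = TRUE))
  }
  dat <- data.frame(th = th, v = v)
  if (model == "reversible") {
    form <- v ~ Vg * (1 - exp(-K1 * th / Vg)) + Vo
    start <- as.list(st)
    lower <- c(K1 = 0, Vg = 1e-6, Vo = 0)
  } else {
    form <- v ~ K * th + Vg * (1 - exp(-(K1 - K) * th / Vg)) + Vo
    start <- as.list(c(K = 1e-3, st))
    lower <- c(K = 0, K1 = 0, Vg = 1e-6, Vo = 0)
  }
  best <- NULL
  for (try in 0:3) {
    s <- start
    if (try > 0) {   # deterministic jitter ladder, no RNG use
      fac <- c(0.5, 1.5, 0.75)[try]
      s <- lapply(start, function(x) max(x * fac, 1e-4))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = s, weights = w,
                        lower = lower[names(s)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      if (fit$convInfo$isConv) break
    }
  }
  if (is.null(best))
    .stopf("MTGA %s fit failed to converge after restarts", model)
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  full_cf <- c(K = 0, K1 = NA_real_, Vg = NA_real_, Vo = NA_real_)
  full_se <- c(K = NA_real_, K1 = NA_real_, Vg = NA_real_, Vo = NA_real_)
  full_cf[names(cf)] <- cf
  full_se[names(cf)] <- se
  fitted <- unname(stats::fitted(fit))
  list(coefficients = full_cf, se = full_se, fitted = fitted,
       residuals = v - fitted, rss = best$rss,
       converged = isTRUE(fit$convInfo$isConv))
}

#' @export
print.mtga_fit <- function(x, digits = 4, ...) {
  cat(sprintf("MTGA fit (%s model), region %s, %d frames, window %g-%g min\n",
              x$model, x$region, x$n, x$window[1L], x$window[2L]))
  cf <- x$coefficients
  cat(sprintf("  K1 = %s mL/g/min (%s mL/hg/min), Vg = %s mL/cm^3, Vo = %s mL/cm^3",
              format(cf[["K1"]], digits = digits),
              format(100 * cf[["K1"]], digits = digits),
              format(cf[["Vg"]], digits = digits),
              format(cf[["Vo"]], digits = digits)))
  if (x$model == "full")
    cat(sprintf(", K = %s mL/g/min", format(cf[["K"]], digits = digits)))
  cat(sprintf("\n  RSS %.3g, %s\n", x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.mtga_fit <- function(object, ...) {
  keep <- switch(object$model,
                 linear = c("K1", "Vo"),
                 reversible = c("K1", "Vg", "Vo"),
                 full = c("K", "K1", "Vg", "Vo"))
  tab <- cbind(Estimate = object$coefficients[keep],
               `Std. Error` = object$se[keep])
  out <- list(model = object$model, region = object$region, table = tab,
              rss = object$rss, n = object$n, window = object$window)
  class(out) <- "summary.mtga_fit"
  out
}

#' @export
print.summary.mtga_fit <- function(x, ...) {
  cat(sprintf("MTGA %s fit, region %s (window %g-%g min, n = %d)\n",
              x$model, x$region, x$window[1L], x$window[2L], x$n))
  print(x$table)
  cat(sprintf("Residual sum of squares: %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.mtga_fit <- function(object, ...) object$coefficients

#' @export
residuals.mtga_fit <- function(object, ...) object$residuals

#' @export
fitted.mtga_fit <- function(object, ...) object$fitted

#' Model curve of a fitted MTGA model
#'
#' @param object An [fit_mtga()] result.
#' @param newdata Optional list or data frame with a `theta` element; defaults
#'   to the fitted coordinates.
#' @param ... Unused.
#' @return Fitted `V(Theta)` values.
#' @export
predict.mtga_fit <- function(object, newdata = NULL, ...) {
  theta <- if (is.null(newdata)) object$theta else
    if (is.list(newdata)) newdata$theta else as.numeric(newdata)
  cf <- object$coefficients
  .mtga_v(theta, cf[["K"]], cf[["K1"]], cf[["Vg"]], cf[["Vo"]])
}

#' Patlak plot of a fitted MTGA model
#'
#' @param x An [fit_mtga()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mtga_fit <- function(x, ...) {
  graphics::plot(x$theta, x$v, xlab = "Normalized time Theta (min)",
                 ylab = "Apparent distribution volume V (mL/cm^3)",
                 main = sprintf("Patlak plot, %s (%s model)", x$region, x$model),
                 ...)
  th <- seq(0, max(x$theta), length.out = 200L)
  graphics::lines(th, predict(x, list(theta = th)), col = "firebrick")
  invisible(x)
}

#' Decide between the irreversible and reversible MTGA forms
#'
#' Operationalizes the model-order decision: when the net clearance `K` of
#' the full irreversible fit is not significantly different from zero
#' (`|K| < z * SE(K)`, default `z = 2`), tracer kinetics are consistent with
#' a single reversible tissue compartment (`k3 ~ 0`) and the reversible form
#' is preferred.
#'
#' @param full_fit An [fit_mtga()] result with `model = "full"`.
#' @param z Decision threshold in SE units.
#' @return `"reversible"` or `"full"`.
#' @export
select_model <- function(full_fit, z = 2) {
  stopifnot(inherits(full_fit, "mtga_fit"))
  if (full_fit$model != "full")
    .stopf("select_model requires a fit of the full model")
  K <- full_fit$coefficients[["K"]]
  seK <- full_fit$se[["K"]]
  if (!is.finite(seK)) .stopf("full fit carries no finite SE for K")
  if (abs(K) < z * seK) "reversible" else "full"
}

#' Plot-ready table for a Patlak plot
#'
#' @param vars An [mtga_variables()] result.
#' @param fit An [fit_mtga()] result (fitted to the same region).
#' @return A data frame with columns `theta`, `v` and `fitted` (the fit's
#'   model curve evaluated at the observed `theta`).
#' @export
patlak_plot_data <- function(vars, fit) {
  stopifnot(inherits(vars, "mtga_vars"), inherits(fit, "mtga_fit"))
  data.frame(theta = vars$theta, v = vars$v,
             fitted = predict(fit, list(theta = vars$theta)))
}
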