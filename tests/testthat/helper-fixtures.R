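# Shared fixtures: default input curves and small helpers used across tests.

default_pib_aif <- function(times = c(seq(0, 4, 0.05), seq(4.25, 12, 0.25))) {
  simulate_aif(aif_shape(), times, parent_params = parent_fraction_params())
}

default_water_blood <- function() {
  simulate_aif(aif_shape(peak_time = 0.4, plateau_fraction = 0.2),
               seq(0, 3.2, by = 1 / 120), tracer = "water")
}

short_pib_frames <- function(t_max = 12) {
  fr <- pib_frame_schedule()
  fr[fr$end <= t_max, ]
}

# Brute-force NNLS oracle: enumerate every support set, solve the
# unconstrained least-squares subproblem on it, keep the best feasible
# (elementwise nonnegative) solution. Exact for small column counts.
nnls_brute_objective <- function(A, b) {
  n <- ncol(A)
  best <- sum(b^2)  # empty support
  for (m in seq_len(2^n - 1)) {
    on <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    xi <- tryCatch(qr.solve(A[, on, drop = FALSE], b),
                   error = function(e) NULL)
    if (is.null(xi) || any(xi < -1e-12)) next
    x <- numeric(n); x[on] <- xi
    best <- min(best, sum((A %*% x - b)^2))
  }
  best
}
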