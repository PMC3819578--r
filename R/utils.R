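# Internal helpers shared across modules.

#' @importFrom stats approx
.interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("non-finite values in %s", what)
  invisible(x)
}
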