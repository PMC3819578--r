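#' Crone-Renkin transfer relations
#'
#' The unidirectional clearance `K1`, blood flow `F` and
#' permeability-surface area product `PS` of a capillary bed are linked by
#' the single-capillary relations
#' `K1 = F (1 - exp(-PS / F))`, `E = K1 / F = 1 - exp(-PS / F)` and
#' `PS = -F log(1 - E)`. All three functions are vectorized and require
#' their inputs to share units (conventionally mL hg^-1 min^-1).
#' `K1 = F` (extraction exactly 1) is rejected as a domain error rather
#' than mapped to an infinite `PS`.
#'
#' @param K1 Unidirectional clearance, same units as `F`, `0 <= K1 < F`.
#' @param F Blood flow, > 0.
#' @param E Extraction fraction, unitless, in `[0, 1)`.
#' @param PS Permeability-surface area product, same units as `F`, >= 0.
#' @return `extraction_fraction()` returns `E = K1/F`; `ps_product()` returns
#'   `PS`; `clearance_from_ps()` returns `K1`.
#' @examples
#' extraction_fraction(K1 = 22, F = 40)        # 0.55
#' ps_product(F = 40, E = 0.55)                # 31.94
#' clearance_from_ps(F = 40, PS = ps_product(40, 0.55))  # back to 22
#' @export
extraction_fraction <- function(K1, F) {
  .check_finite(K1, "K1"); .check_finite(F, "F")
  if (any(F <= 0)) .stopf("F must be positive")
  if (any(K1 < 0)) .stopf("K1 must be nonnegative")
  if (any(K1 > F))
    .stopf("K1 exceeds F: extraction fraction would exceed 1")
  K1 / F
}

#' @rdname extraction_fraction
#' @export
ps_product <- function(F, E) {
  .check_finite(F, "F"); .check_finite(E, "E")
  if (any(F <= 0)) .stopf("F must be positive")
  if (any(E < 0)) .stopf("E must be nonnegative")
  if (any(E >= 1)) .stopf("E must be below 1 (PS is undefined at E = 1)")
  -F * log(1 - E)
}

#' @rdname extraction_fraction
#' @export
clearance_from_ps <- function(F, PS) {
  .check_finite(F, "F"); .check_finite(PS, "PS")
  if (any(F <= 0)) .stopf("F must be positive")
  if (any(PS < 0)) .stopf("PS must be nonnegative")
  F * (1 - exp(-PS / F))
}

#' Append extraction and permeability columns to a metrics table
#'
#' Vectorized batch form of the Crone-Renkin relations: given a data frame
#' with flow `F` and clearance `K1` columns (shared units), appends the
#' extraction fraction `E` and permeability-surface area product `PS`.
#' Rows where `K1 >= F` or `F <= 0` yield `NA` with a warning rather than
#' an error, so one bad region does not abort a batch.
#'
#' @param df A data frame with numeric columns `F` and `K1`.
#' @return `df` with columns `E` (fraction) and `PS` appended.
#' @export
transfer_metrics <- function(df) {
  stopifnot(is.data.frame(df), all(c("F", "K1") %in% names(df)))
  ok <- is.finite(df$F) & is.finite(df$K1) & df$F > 0 &
    df$K1 >= 0 & df$K1 < df$F
  if (any(!ok))
    warning(sprintf("%d row(s) violate 0 <= K1 < F; E and PS set to NA",
                    sum(!ok)), call. = FALSE)
  E <- PS <- rep(NA_real_, nrow(df))
  E[ok] <- df$K1[ok] / df$F[ok]
  PS[ok] <- -df$F[ok] * log(1 - E[ok])
  df$E <- E
  df$PS <- PS
  df
}
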