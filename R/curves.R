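#' Arterial input curve
#'
#' Container for an arterial plasma (or whole-blood, for water sessions)
#' activity curve: sample times in minutes post-injection and decay-corrected
#' activity concentration in kBq/mL, with an optional parent (unmetabolized
#' tracer) fraction aligned with the sample times.
#'
#' @param times Sample times in minutes, strictly increasing.
#' @param activity Activity concentration in kBq/mL, nonnegative, same length
#'   as `times`.
#' @param parent_fraction Optional unitless fractions in \[0, 1\]: the
#'   proportion of plasma activity that is unchanged tracer. Must equal 1 at
#'   the first sample and be nonincreasing.
#' @param tracer Tracer label, `"PiB"` or `"water"`.
#' @return An object of class `plasma_curve`: a list with elements `times`,
#'   `activity`, `parent_fraction` (or `NULL`) and `tracer`.
#' @examples
#' aif <- plasma_curve(c(0, 0.5, 1, 2, 4), c(0, 80, 40, 15, 10))
#' aif
#' @export
plasma_curve <- function(times, activity, parent_fraction = NULL,
                         tracer = c("PiB", "water")) {
  tracer <- match.arg(tracer)
  times <- as.numeric(times)
  activity <- as.numeric(activity)
  if (length(times) < 2L || length(activity) != length(times))
    .stopf("times and activity must be equal-length vectors (>= 2 samples)")
  .check_finite(times, "times")
  .check_finite(activity, "activity")
  if (any(diff(times) <= 0)) .stopf("times must be strictly increasing")
  if (any(activity < 0)) .stopf("activity must be nonnegative")
  if (!is.null(parent_fraction)) {
    parent_fraction <- as.numeric(parent_fraction)
    if (length(parent_fraction) != length(times))
      .stopf("parent_fraction must align with times")
    if (any(parent_fraction < 0 | parent_fraction > 1))
      .stopf("parent_fraction must lie in [0, 1]")
    if (abs(parent_fraction[1L] - 1) > 1e-6)
      .stopf("parent_fraction must equal 1 at the first sample")
    if (any(diff(parent_fraction) > 1e-12))
      .stopf("parent_fraction must be nonincreasing")
  }
  structure(list(times = times, activity = activity,
                 parent_fraction = parent_fraction, tracer = tracer),
            class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> %s, %d samples over %.2f-%.2f min, peak %.1f kBq/mL%s\n",
              x$tracer, length(x$times), min(x$times), max(x$times),
              max(x$activity),
              if (is.null(x$parent_fraction)) "" else ", parent fraction present"))
  invisible(x)
}

#' Trapezoidal area under a plasma curve
#'
#' @param curve A [plasma_curve()].
#' @param corrected If `TRUE` and the curve carries a parent fraction,
#'   integrate the metabolite-corrected (parent) activity.
#' @return Area under the curve in kBq min/mL.
#' @export
plasma_auc <- function(curve, corrected = FALSE) {
  a <- curve$activity
  if (corrected && !is.null(curve$parent_fraction))
    a <- a * curve$parent_fraction
  pracma::trapz(curve$times, a)
}

#' Regional time-activity curve
#'
#' Frame-averaged tissue activity concentration for one region of a dynamic
#' PET session: contiguous, nonoverlapping frames (minutes) and the mean
#' activity in kBq/cm^3 tissue within each frame.
#'
#' @param frame_start,frame_end Frame boundaries in minutes; frames sorted,
#'   nonoverlapping, with `frame_end > frame_start` throughout.
#' @param activity Frame-averaged activity, kBq/cm^3, one value per frame.
#' @param region Region label, e.g. `"FL"`, `"CTX"`, `"CERB"`.
#' @return An object of class `tac`.
#' @examples
#' tac(c(0, 1, 2), c(1, 2, 3), c(5.2, 8.1, 7.9), region = "CTX")
#' @export
tac <- function(frame_start, frame_end, activity, region = "CTX") {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  activity <- as.numeric(activity)
  n <- length(frame_start)
  if (length(frame_end) != n || length(activity) != n || n < 1L)
    .stopf("frame_start, frame_end and activity must be equal-length vectors")
  .check_finite(c(frame_start, frame_end), "frame boundaries")
  .check_finite(activity, "activity")
  if (any(frame_end <= frame_start)) .stopf("frame_end must exceed frame_start")
  if (is.unsorted(frame_start, strictly = TRUE)) .stopf("frames must be sorted")
  if (n > 1L && any(frame_start[-1L] < frame_end[-n] - 1e-9))
    .stopf("frames must not overlap")
  structure(list(frame_start = frame_start, frame_end = frame_end,
                 activity = activity, region = as.character(region)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region %s, %d frames over %.2f-%.2f min, peak %.1f kBq/cm^3\n",
              x$region, length(x$activity), min(x$frame_start),
              max(x$frame_end), max(x$activity)))
  invisible(x)
}

frame_mid <- function(tac) (tac$frame_start + tac$frame_end) / 2
frame_dur <- function(tac) tac$frame_end - tac$frame_start

#' Read and write plasma curves as CSV
#'
#' The CSV layout has columns `time_min`, `activity_kBq_per_mL` and an
#' optional `parent_fraction`, with a header row, UTF-8 encoding and "."
#' as the decimal separator.
#'
#' @param path File path.
#' @param tracer Tracer label passed to [plasma_curve()] when reading.
#' @return `read_plasma_csv()` returns a [plasma_curve()];
#'   `write_plasma_csv()` returns `path` invisibly.
#' @export
read_plasma_csv <- function(path, tracer = "PiB") {
  df <- utils::read.csv(path)
  need <- c("time_min", "activity_kBq_per_mL")
  if (!all(need %in% names(df)))
    .stopf("plasma CSV must have columns %s", paste(need, collapse = ", "))
  pf <- if ("parent_fraction" %in% names(df)) df$parent_fraction else NULL
  plasma_curve(df$time_min, df$activity_kBq_per_mL, pf, tracer = tracer)
}

#' @param curve A [plasma_curve()] to write.
#' @rdname read_plasma_csv
#' @export
write_plasma_csv <- function(curve, path) {
  df <- data.frame(time_min = curve$times,
                   activity_kBq_per_mL = curve$activity)
  if (!is.null(curve$parent_fraction))
    df$parent_fraction <- curve$parent_fraction
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write regional TACs as CSV
#'
#' Layout: columns `frame_start_min`, `frame_end_min`, then one activity
#' column per region.
#'
#' @param path File path.
#' @return `read_tac_csv()` returns a named list of [tac()] objects, one per
#'   region column; `write_tac_csv()` returns `path` invisibly.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame_start_min", "frame_end_min")
  if (!all(need %in% names(df)))
    .stopf("TAC CSV must have columns %s", paste(need, collapse = ", "))
  regions <- setdiff(names(df), need)
  if (length(regions) == 0L) .stopf("TAC CSV has no region columns")
  out <- lapply(regions, function(r)
    tac(df$frame_start_min, df$frame_end_min, df[[r]], region = r))
  names(out) <- regions
  out
}

#' @param tacs A [tac()] or named list of `tac` objects sharing one frame
#'   schedule.
#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- stats::setNames(list(tacs), tacs$region)
  ref <- tacs[[1L]]
  df <- data.frame(frame_start_min = ref$frame_start,
                   frame_end_min = ref$frame_end)
  for (nm in names(tacs)) df[[nm]] <- tacs[[nm]]$activity
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
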