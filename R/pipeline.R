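#' Analysis pipeline configuration
#'
#' @param mtga_model MTGA model used for the PiB clearance (default
#'   `"reversible"`, the single-tissue-compartment form).
#' @param mtga_window PiB analysis window in real minutes (default 0-4 min,
#'   the period before labeled metabolites corrupt the plasma input).
#' @param cbf_window Water analysis window, minutes.
#' @param parent_correction Use the metabolite-corrected plasma input for
#'   the MTGA variables (default `FALSE`: metabolites are negligible within
#'   the 0-4 min window).
#' @param include_v0 Include the vascular column in the water model.
#' @param verbose Log stage completion messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mtga_model = "reversible", mtga_window = c(0, 4),
                            cbf_window = c(0, 3), parent_correction = FALSE,
                            include_v0 = TRUE, verbose = FALSE) {
  structure(list(mtga_model = mtga_model, mtga_window = mtga_window,
                 cbf_window = cbf_window,
                 parent_correction = parent_correction,
                 include_v0 = include_v0, verbose = verbose),
            class = "pipeline_config")
}

#' Analyse one subject
#'
#' Runs the full per-subject analysis on a data bundle holding a water and
#' a PiB session: regional flow `F` from [fit_cbf()], regional PiB clearance
#' `K1` from [fit_mtga()] (reversible model over the configured window),
#' and extraction fraction and permeability-surface area product from the
#' Crone-Renkin relations. A failure in one region is logged as a warning
#' and yields `NA`s for that region rather than aborting the subject.
#'
#' @param bundle A subject bundle as produced by [generate_cohort()]:
#'   `list(subject_id, group, water = list(blood, tacs), pib = list(plasma,
#'   tacs))` with `tacs` named lists of [tac()] objects.
#' @param config A [pipeline_config()].
#' @return A data frame with one row per region: `subject_id`, `group`,
#'   `region`, `F`, `K1` (both mL hg^-1 min^-1), `se_K1`, `E`, `PS`,
#'   `k2_water`, `V0_water`, `mtga_rss`.
#' @export
run_subject <- function(bundle, config = pipeline_config()) {
  if (is.null(bundle$water) || is.null(bundle$pib))
    .stopf("subject bundle must contain both a water and a PiB session")
  regions <- intersect(names(bundle$water$tacs), names(bundle$pib$tacs))
  if (length(regions) == 0L) .stopf("no common regions across sessions")
  rows <- lapply(regions, function(r) {
    row <- data.frame(subject_id = bundle$subject_id, group = bundle$group,
                      region = r, F = NA_real_, K1 = NA_real_,
                      se_K1 = NA_real_, E = NA_real_, PS = NA_real_,
                      k2_water = NA_real_, V0_water = NA_real_,
                      mtga_rss = NA_real_)
    tryCatch({
      cbf <- fit_cbf(bundle$water$tacs[[r]], bundle$water$blood,
                     window = config$cbf_window,
                     include_v0 = config$include_v0)
      mv <- mtga_variables(bundle$pib$tacs[[r]], bundle$pib$plasma,
                           parent_correction = config$parent_correction)
      mf <- fit_mtga(mv, model = config$mtga_model,
                     window = config$mtga_window)
      row$F <- cbf$F
      row$K1 <- 100 * mf$coefficients[["K1"]]
      row$se_K1 <- 100 * mf$se[["K1"]]
      row$k2_water <- cbf$k2
      row$V0_water <- cbf$V0
      row$mtga_rss <- mf$rss
      if (row$F > 0 && row$K1 >= 0 && row$K1 < row$F) {
        row$E <- row$K1 / row$F
        row$PS <- -row$F * log(1 - row$E)
      } else if (row$F == 0 && row$K1 == 0) {
        row$E <- 0; row$PS <- 0
      }
      row
    }, error = function(e) {
      warning(sprintf("subject %s region %s failed: %s", bundle$subject_id,
                      r, conditionMessage(e)), call. = FALSE)
      row
    })
  })
  out <- do.call(rbind, rows)
  if (isTRUE(config$verbose))
    message(sprintf("subject %s: %d region(s) analysed", bundle$subject_id,
                    sum(is.finite(out$F))))
  out
}

#' Analyse a whole cohort
#'
#' Applies [run_subject()] to every subject of a [generate_cohort()] result
#' (or any list of subject bundles) and summarizes the groups.
#'
#' @param cohort A [generate_cohort()] result or list of subject bundles.
#' @param config A [pipeline_config()].
#' @return A list with `subject_metrics` (per-subject data frame) and
#'   `group_summary` ([summarize_groups()] table).
#' @export
run_cohort <- function(cohort, config = pipeline_config()) {
  subjects <- if (!is.null(cohort$subjects)) cohort$subjects else cohort
  metrics <- do.call(rbind, lapply(subjects, run_subject, config = config))
  rownames(metrics) <- NULL
  list(subject_metrics = metrics,
       group_summary = summarize_groups(metrics))
}

#' Group summary table with between-group tests
#'
#' Produces the group-comparison layout of the study design: per region and
#' variable, the group means and standard errors of the mean
#' (`SEM = SD / sqrt(n)`) and the two-sided P value of Welch's
#' unequal-variance two-sample t-test for the group difference. The
#' extraction fraction is reported as a percentage.
#'
#' @param metrics A per-subject metrics data frame from [run_subject()]
#'   (columns `group`, `region` and the summarized variables).
#' @param variables Variables to summarize.
#' @return A data frame with one row per region x variable: `region`,
#'   `variable`, `mean_<g>`, `sem_<g>` for each group, and `p_value`.
#' @examples
#' m <- data.frame(group = rep(c("HC", "AD"), each = 3), region = "CTX",
#'                 F = c(50, 52, 54, 38, 40, 42))
#' summarize_groups(m, variables = "F")
#' @export
summarize_groups <- function(metrics, variables = c("F", "K1", "E", "PS")) {
  stopifnot(is.data.frame(metrics),
            all(c("group", "region") %in% names(metrics)))
  variables <- intersect(variables, names(metrics))
  if (length(variables) == 0L) .stopf("no summarizable variables found")
  groups <- unique(metrics$group)
  if (length(groups) != 2L) .stopf("exactly two groups are required")
  g1 <- groups[1L]; g2 <- groups[2L]
  rows <- list()
  for (r in unique(metrics$region)) {
    for (v in variables) {
      x1 <- metrics[metrics$region == r & metrics$group == g1, v]
      x2 <- metrics[metrics$region == r & metrics$group == g2, v]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
      if (length(x1) < 2L || length(x2) < 2L)
        .stopf("fewer than 2 subjects with finite %s in region %s", v, r)
      scale <- if (v == "E") 100 else 1   # extraction reported in percent
      x1 <- scale * x1; x2 <- scale * x2
      p <- tryCatch(stats::t.test(x1, x2)$p.value,
                    error = function(e)
                      if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else NA_real_)
      row <- data.frame(region = r, variable = v,
                        m1 = mean(x1), s1 = stats::sd(x1) / sqrt(length(x1)),
                        m2 = mean(x2), s2 = stats::sd(x2) / sqrt(length(x2)),
                        p_value = p)
      names(row)[3:6] <- c(paste0(c("mean_", "sem_"), g1),
                           paste0(c("mean_", "sem_"), g2))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize plasma curves to a common area under the curve
#'
#' Rescales each curve so that its trapezoidal AUC equals the cohort-average
#' AUC, the normalization used to overlay arterial curves across subjects.
#'
#' @param curves A list of [plasma_curve()] objects with positive AUCs.
#' @return The rescaled list.
#' @export
auc_normalize <- function(curves) {
  if (inherits(curves, "plasma_curve")) curves <- list(curves)
  aucs <- vapply(curves, plasma_auc, numeric(1))
  if (any(aucs <= 0)) .stopf("every curve must have positive AUC")
  target <- mean(aucs)
  lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    plasma_curve(cu$times, cu$activity * target / aucs[i],
                 cu$parent_fraction, tracer = cu$tracer)
  })
}

#' Windowed group uptake contrast
#'
#' For each region and time window, computes the fractional difference of
#' tracer accumulation between a test group and a reference group:
#' `(mean test accumulation) / (mean reference accumulation) - 1`, where a
#' subject's accumulation is the frame-duration-weighted mean activity of
#' the frames whose mid-times fall in the window.
#'
#' @param subject_tacs List (one element per subject) of named lists of
#'   [tac()] objects sharing region names.
#' @param groups Character vector of group labels, one per subject.
#' @param windows List of `c(lo, hi)` windows in minutes.
#' @param ref_group,test_group Group labels; the contrast is test vs
#'   reference.
#' @return A data frame with `region`, `window_lo`, `window_hi`, `contrast`.
#' @export
windowed_uptake_contrast <- function(subject_tacs, groups, windows,
                                     ref_group = "HC", test_group = "AD") {
  stopifnot(length(subject_tacs) == length(groups))
  if (inherits(windows[[1L]], "numeric") && !is.list(windows))
    windows <- list(windows)
  regions <- names(subject_tacs[[1L]])
  rows <- list()
  for (w in windows) {
    if (length(w) != 2L || w[2L] <= w[1L]) .stopf("invalid window")
    for (r in regions) {
      acc <- vapply(subject_tacs, function(s) {
        tc <- s[[r]]
        mids <- frame_mid(tc); dur <- frame_dur(tc)
        sel <- mids >= w[1L] & mids <= w[2L]
        if (!any(sel))
          .stopf("window [%g, %g] contains no frames", w[1L], w[2L])
        stats::weighted.mean(tc$activity[sel], dur[sel])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, window_lo = w[1L], window_hi = w[2L],
        contrast = mean(acc[groups == test_group]) /
          mean(acc[groups == ref_group]) - 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Squared correlation of paired regional differences
#'
#' Pearson R^2 between per-region group differences of two quantities
#' (e.g. flow difference vs uptake difference). With only three regions the
#' value is descriptive, and the result is flagged as such.
#'
#' @param delta_flow,delta_uptake Paired per-region difference vectors,
#'   length >= 3.
#' @return A list with `r_squared`, `n_regions` and `descriptive` (`TRUE`
#'   when only 3 pairs are available).
#' @export
regional_difference_correlation <- function(delta_flow, delta_uptake) {
  if (length(delta_flow) != length(delta_uptake))
    .stopf("inputs must be paired")
  if (length(delta_flow) < 3L) .stopf("at least 3 paired regions required")
  if (stats::sd(delta_flow) == 0 || stats::sd(delta_uptake) == 0)
    .stopf("correlation undefined for constant differences")
  list(r_squared = stats::cor(delta_flow, delta_uptake)^2,
       n_regions = length(delta_flow),
       descriptive = length(delta_flow) == 3L)
}
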