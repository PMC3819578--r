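#' Cohort simulation specification
#'
#' Describes one subject group for the synthetic-cohort generator: the
#' number of subjects and, per region, the between-subject means and SDs of
#' blood flow `F`, PiB clearance `K1` (both mL hg^-1 min^-1, the unit of the
#' group summary tables) and the PiB vascular volume `Vo` (mL/cm^3).
#' Per-subject regional parameters are drawn as independent normals
#' truncated at 0; `K1` is additionally capped at `0.95 F` so every subject
#' satisfies the Crone-Renkin constraint `K1 < F`.
#'
#' @param group_name Group label, e.g. `"HC"`.
#' @param n_subjects Number of subjects, >= 1.
#' @param regions Data frame with columns `region`, `F_mean`, `F_sd`,
#'   `K1_mean`, `K1_sd`, `Vo_mean`, `Vo_sd`.
#' @param noise_scale Measurement-noise magnitude passed to
#'   [simulate_tissue_tac()].
#' @return An object of class `cohort_spec`.
#' @seealso [hc_cohort_spec()], [ad_cohort_spec()] for ready-made groups
#'   emulating a healthy-control and an Alzheimer cohort.
#' @export
cohort_spec <- function(group_name, n_subjects, regions, noise_scale = 0.1) {
  if (n_subjects < 1L) .stopf("n_subjects must be >= 1")
  regions <- as.data.frame(regions)
  need <- c("region", "F_mean", "F_sd", "K1_mean", "K1_sd", "Vo_mean", "Vo_sd")
  if (!all(need %in% names(regions)))
    .stopf("regions must have columns %s", paste(need, collapse = ", "))
  sds <- unlist(regions[c("F_sd", "K1_sd", "Vo_sd")])
  if (any(sds < 0)) .stopf("SDs must be nonnegative")
  structure(list(group_name = as.character(group_name),
                 n_subjects = as.integer(n_subjects),
                 regions = regions, noise_scale = noise_scale),
            class = "cohort_spec")
}

# Group means (mL/hg/min) for the three regions of the study design, with
# between-subject SDs recovered from the reported SEMs (SD = SEM sqrt(n)).
.hc_regions <- function() data.frame(
  region = c("FL", "CTX", "CERB"),
  F_mean = c(54, 52, 54), F_sd = c(2, 2, 2) * sqrt(6),
  K1_mean = c(28, 24, 27), K1_sd = c(3, 2, 2) * sqrt(6),
  Vo_mean = 0.05, Vo_sd = 0.01)

.ad_regions <- function() data.frame(
  region = c("FL", "CTX", "CERB"),
  F_mean = c(43, 40, 47), F_sd = c(3, 3, 2) * sqrt(5),
  K1_mean = c(25, 22, 26), K1_sd = c(2, 2, 2) * sqrt(5),
  Vo_mean = 0.05, Vo_sd = 0.01)

#' Study-design group specifications
#'
#' Ready-made [cohort_spec()]s emulating the two groups of the study design:
#' six healthy controls (`hc_cohort_spec()`) and five Alzheimer patients
#' (`ad_cohort_spec()`), with frontal-lobe, cortex and cerebellum means of
#' flow and clearance centered on the group summary values and
#' between-subject SDs recovered from the reported SEMs.
#'
#' @param n_subjects Number of subjects (defaults: 6 HC, 5 AD).
#' @param noise_scale Measurement-noise magnitude.
#' @return A [cohort_spec()].
#' @export
hc_cohort_spec <- function(n_subjects = 6, noise_scale = 0.1)
  cohort_spec("HC", n_subjects, .hc_regions(), noise_scale)

#' @rdname hc_cohort_spec
#' @export
ad_cohort_spec <- function(n_subjects = 5, noise_scale = 0.1)
  cohort_spec("AD", n_subjects, .ad_regions(), noise_scale)

# Fixed simulation constants: PiB precursor-pool volume (sets k2 = K1/Vg),
# water partition coefficient (sets k2_w = F/lambda) and water vascular
# volume. Chosen once as physiologically plausible study conditions.
.PIB_VG <- 1.0       # mL/cm^3
.WATER_LAMBDA <- 0.9 # mL/g
.WATER_V0 <- 0.03    # mL/cm^3

.default_pib_sampling <- function()
  c(seq(0, 4, by = 0.05), seq(4.25, 10, by = 0.25),
    seq(10.5, 20, by = 0.5), seq(21, 90, by = 1))

.default_water_sampling <- function() seq(0, 3.2, by = 1 / 120)

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject regional kinetic parameters from the group
#' specifications, then simulates for every subject a 3-min water session
#' (arterial blood curve plus regional TACs with flow-driven one-tissue
#' kinetics, `k2 = F / 0.9`) and a 90-min PiB session (triphasic arterial
#' curve with Hill parent fraction plus regional one-tissue TACs with
#' `k2 = K1 / Vg`, `Vg = 1.0` mL/cm^3, driven by the parent input since
#' labeled metabolites do not cross the blood-brain barrier). The
#' generating truth table is returned alongside the data so parameter
#' recovery can be tested.
#'
#' @param specs A [cohort_spec()] or list of them.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param water_frames,pib_frames Frame schedules (data frames with `start`,
#'   `end` in minutes).
#' @param aif_shape_pib,aif_shape_water AIF shapes for the two sessions.
#' @param parent_params Parent-fraction parameters for the PiB arterial
#'   curve.
#' @param dt_water,dt_pib Internal integration steps, minutes.
#' @return A list with `subjects` (per-subject bundles, each holding
#'   `subject_id`, `group`, `water = list(blood, tacs)` and
#'   `pib = list(plasma, tacs)`) and `truth` (data frame `subject_id`,
#'   `group`, `region`, `F`, `K1`, `k2`, `Vo`, `seed`; `F` and `K1` in
#'   mL hg^-1 min^-1).
#' @examples
#' coh <- generate_cohort(list(hc_cohort_spec(2), ad_cohort_spec(2)), seed = 7)
#' coh$truth[1:3, ]
#' @export
generate_cohort <- function(specs, seed = 1L,
                            water_frames = water_frame_schedule(),
                            pib_frames = pib_frame_schedule(),
                            aif_shape_pib = aif_shape(),
                            aif_shape_water = aif_shape(peak_time = 0.4,
                                                        plateau_fraction = 0.2),
                            parent_params = parent_fraction_params(),
                            dt_water = 0.005, dt_pib = 0.01) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  if (length(specs) == 0L) .stopf("specs must be nonempty")
  .with_seed(as.integer(seed), {
    subjects <- list()
    truth <- list()
    sid <- 0L
    for (spec in specs) {
      for (i in seq_len(spec$n_subjects)) {
        sid <- sid + 1L
        id <- sprintf("%s%02d", spec$group_name, i)
        rg <- spec$regions
        Fh <- pmax(stats::rnorm(nrow(rg), rg$F_mean, rg$F_sd), 0)
        K1h <- pmax(stats::rnorm(nrow(rg), rg$K1_mean, rg$K1_sd), 0)
        K1h <- pmin(K1h, 0.95 * Fh)
        Voh <- pmax(stats::rnorm(nrow(rg), rg$Vo_mean, rg$Vo_sd), 0)
        amp <- exp(stats::rnorm(1, 0, 0.05))  # subject-level injected dose
        water_blood <- simulate_aif(
          aif_shape(aif_shape_water$peak_time,
                    aif_shape_water$peak_amplitude * amp,
                    aif_shape_water$bolus_sharpness,
                    aif_shape_water$plateau_fraction,
                    aif_shape_water$plateau_onset),
          .default_water_sampling(), tracer = "water")
        pib_plasma <- simulate_aif(
          aif_shape(aif_shape_pib$peak_time,
                    aif_shape_pib$peak_amplitude * amp,
                    aif_shape_pib$bolus_sharpness,
                    aif_shape_pib$plateau_fraction,
                    aif_shape_pib$plateau_onset),
          .default_pib_sampling(), parent_params = parent_params)
        wtacs <- ptacs <- list()
        for (j in seq_len(nrow(rg))) {
          f_g <- Fh[j] / 100   # to mL/g/min
          k1_g <- K1h[j] / 100
          wtruth <- kinetic_truth(K1 = f_g, k2 = f_g / .WATER_LAMBDA,
                                  Vo = .WATER_V0)
          ptruth <- kinetic_truth(K1 = k1_g, k2 = k1_g / .PIB_VG, Vo = Voh[j])
          wtacs[[rg$region[j]]] <- simulate_tissue_tac(
            water_blood, wtruth, water_frames,
            noise_scale = spec$noise_scale, region = rg$region[j],
            dt = dt_water)
          ptacs[[rg$region[j]]] <- simulate_tissue_tac(
            pib_plasma, ptruth, pib_frames,
            noise_scale = spec$noise_scale, region = rg$region[j],
            dt = dt_pib, use_parent = TRUE)
          truth[[length(truth) + 1L]] <- data.frame(
            subject_id = id, group = spec$group_name, region = rg$region[j],
            F = Fh[j], K1 = K1h[j], k2 = k1_g / .PIB_VG, Vo = Voh[j],
            seed = as.integer(seed))
        }
        subjects[[id]] <- list(subject_id = id, group = spec$group_name,
                               water = list(blood = water_blood, tacs = wtacs),
                               pib = list(plasma = pib_plasma, tacs = ptacs))
      }
    }
    list(subjects = subjects, truth = do.call(rbind, truth))
  })
}

#' Power of the group CBF comparison under the study design
#'
#' Simulates replicate two-group cohorts for a single cortical region,
#' estimates each subject's flow with [fit_cbf()] from a noisy simulated
#' water session, applies Welch's two-sample t-test to the fitted flows and
#' returns the proportion of replicates in which the group difference is
#' detected at `alpha`.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param hc,ad Lists with `mean`, `sd` (mL hg^-1 min^-1) and `n` for each
#'   group; defaults are the cortical flow summary of the study design
#'   (52 +/- 2 SEM, n = 6 vs 40 +/- 3 SEM, n = 5).
#' @param noise_scale Measurement noise of the simulated water TACs.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param dt Integration step of the water simulation, minutes.
#' @return A list with `power` (detection proportion), `p_values` and
#'   `n_replicates`.
#' @export
cbf_group_power <- function(n_replicates = 500,
                            hc = list(mean = 52, sd = 2 * sqrt(6), n = 6),
                            ad = list(mean = 40, sd = 3 * sqrt(5), n = 5),
                            noise_scale = 0.1, alpha = 0.05, seed = 1L,
                            dt = 0.005) {
  frames <- water_frame_schedule()
  blood <- simulate_aif(aif_shape(peak_time = 0.4, plateau_fraction = 0.2),
                        .default_water_sampling(), tracer = "water")
  fit_one <- function(f_hg) {
    f_g <- f_hg / 100
    tt <- kinetic_truth(K1 = f_g, k2 = f_g / .WATER_LAMBDA, Vo = .WATER_V0)
    tac <- simulate_tissue_tac(blood, tt, frames, noise_scale = noise_scale,
                               dt = dt)
    fit_cbf(tac, blood)$F
  }
  p <- .with_seed(as.integer(seed), {
    vapply(seq_len(n_replicates), function(r) {
      f_hc <- pmax(stats::rnorm(hc$n, hc$mean, hc$sd), 0)
      f_ad <- pmax(stats::rnorm(ad$n, ad$mean, ad$sd), 0)
      est_hc <- vapply(f_hc, fit_one, numeric(1))
      est_ad <- vapply(f_ad, fit_one, numeric(1))
      stats::t.test(est_hc, est_ad)$p.value
    }, numeric(1))
  })
  list(power = mean(p < alpha), p_values = p, n_replicates = n_replicates)
}
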