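#' Default stage-effect matrix for the synthetic cohort generator
#'
#' Additive elevation of regional BP_ND (binding potential units) for a
#' patient at each true stage, following the cumulative pallidal ->
#' frontal/cerebellar -> occipital sequence: the pallidum is involved from
#' stage I (mild) and II (severe), frontal and cerebellar regions from stage
#' III/IV, occipital subregions from stage V/VI. Rows are subregions, columns
#' stages I--VI; each row is non-decreasing across stages (cumulative
#' pathology).
#'
#' @param mild,severe elevations (BP_ND units) for mild/moderate and
#'   moderate/severe involvement. Defaults of 0.25 and 0.50 are roughly 2.5
#'   and 5 control SDs for the default regional spreads.
#' @return 6 x 6 numeric matrix, dimnames subregion x stage.
#' @export
stage_effect_matrix <- function(mild = 0.25, severe = 0.50) {
  stopifnot(mild >= 0, severe >= mild)
  regions <- psp_subregions()$subregion
  m <- matrix(0, nrow = 6, ncol = 6,
              dimnames = list(regions, c("I", "II", "III", "IV", "V", "VI")))
  m["globus_pallidus", ] <- c(mild, rep(severe, 5))
  for (r in c("cerebellar_wm", "dentate", "middle_frontal")) {
    m[r, ] <- c(0, 0, mild, rep(severe, 3))
  }
  for (r in c("lingual", "cuneus")) {
    m[r, ] <- c(0, 0, 0, 0, mild, severe)
  }
  m
}

#' Configuration of the synthetic PSP cohort generator
#'
#' Describes the statistical structure of a synthetic tau-PET cohort: a
#' control group and a patient group with stage-dependent cumulative regional
#' BP_ND elevation, additive age and scanner effects, PSPRS clinical scores,
#' and a brain-donation subset with postmortem stages and PET-to-death
#' intervals. The defaults emulate the descriptives of the cohort the staging
#' analysis was designed for: 39 controls (age 65.8 +/- 8.2 y), 42 patients
#' (age 70.3 +/- 7.0 y; PSPRS 36.6 +/- 14.2), roughly 9/42 donors with
#' intervals of 2.45 +/- 0.98 years.
#'
#' @param n_controls,n_patients group sizes.
#' @param stage_distribution probability vector over true stages I--VI
#'   (length 6, nonnegative, sums to 1).
#' @param control_region_means,control_region_sds named numeric vectors of
#'   baseline BP_ND mean and SD per subregion (names as `psp_subregions()`).
#' @param stage_effect_sizes subregion x stage matrix of additive BP_ND
#'   elevations; each row must be non-decreasing across stages (cumulative
#'   pathology). See [stage_effect_matrix()].
#' @param age_slope BP_ND change per year of age (applies to everyone).
#' @param scanner_offset additive BP_ND offset for PET/MRI scanners.
#' @param control_age_mean,control_age_sd,patient_age_mean,patient_age_sd
#'   age distributions (years).
#' @param scanner_probs_controls,scanner_probs_patients probabilities of the
#'   scanner classes `petmr`, `petct`, `pet`.
#' @param psprs_mean,psprs_sd PSPRS distribution for patients (0--100 scale).
#' @param psprs_stage_coupling PSPRS points added per unit of (true stage -
#'   3.5); 0 (the default) generates severity independent of stage, matching
#'   the null association the staging analysis observed.
#' @param donation_fraction fraction of patients with postmortem follow-up.
#' @param interval_mean_y,interval_sd_y PET-to-death interval distribution
#'   (years), truncated below at 0.1.
#' @param progression_rate expected postmortem stage increments per year of
#'   interval (Poisson); encodes in vivo stage <= postmortem stage as the
#'   typical case.
#' @param patient_noise_scale multiplier on `control_region_sds` for the
#'   patients' regional noise.
#' @param subject_effect_sd SD of an optional subject-level random effect
#'   shared across regions (0 = independent regions).
#' @param lr_noise_sd SD of the left/right hemispheric asymmetry noise.
#' @param seed integer seed used by [generate_cohort()].
#' @return list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_controls = 10, n_patients = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_controls = 39,
                          n_patients = 42,
                          stage_distribution = c(0.05, 0.19, 0.21, 0.40,
                                                 0.12, 0.03),
                          control_region_means = c(
                            globus_pallidus = 0.55, cerebellar_wm = 0.25,
                            dentate = 0.30, middle_frontal = 0.15,
                            lingual = 0.20, cuneus = 0.18),
                          control_region_sds = c(
                            globus_pallidus = 0.10, cerebellar_wm = 0.10,
                            dentate = 0.10, middle_frontal = 0.10,
                            lingual = 0.10, cuneus = 0.10),
                          stage_effect_sizes = stage_effect_matrix(),
                          age_slope = 0.004,
                          scanner_offset = 0.05,
                          control_age_mean = 65.8, control_age_sd = 8.2,
                          patient_age_mean = 70.3, patient_age_sd = 7.0,
                          scanner_probs_controls = c(petmr = 24, petct = 7,
                                                     pet = 8) / 39,
                          scanner_probs_patients = c(petmr = 22, petct = 13,
                                                     pet = 7) / 42,
                          psprs_mean = 36.6, psprs_sd = 14.2,
                          psprs_stage_coupling = 0,
                          donation_fraction = 9 / 42,
                          interval_mean_y = 2.45, interval_sd_y = 0.98,
                          progression_rate = 0.4,
                          patient_noise_scale = 1,
                          subject_effect_sd = 0,
                          lr_noise_sd = 0.02,
                          seed = 1L) {
  cfg <- list(n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              stage_distribution = stage_distribution,
              control_region_means = control_region_means,
              control_region_sds = control_region_sds,
              stage_effect_sizes = stage_effect_sizes,
              age_slope = age_slope, scanner_offset = scanner_offset,
              control_age_mean = control_age_mean,
              control_age_sd = control_age_sd,
              patient_age_mean = patient_age_mean,
              patient_age_sd = patient_age_sd,
              scanner_probs_controls = scanner_probs_controls,
              scanner_probs_patients = scanner_probs_patients,
              psprs_mean = psprs_mean, psprs_sd = psprs_sd,
              psprs_stage_coupling = psprs_stage_coupling,
              donation_fraction = donation_fraction,
              interval_mean_y = interval_mean_y,
              interval_sd_y = interval_sd_y,
              progression_rate = progression_rate,
              patient_noise_scale = patient_noise_scale,
              subject_effect_sd = subject_effect_sd,
              lr_noise_sd = lr_noise_sd,
              seed = as.integer(seed))
  .validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[c("stage_distribution", "control_region_means",
                      "control_region_sds", "age_slope", "scanner_offset",
                      "psprs_mean", "psprs_sd", "donation_fraction",
                      "interval_mean_y", "interval_sd_y",
                      "progression_rate")])
  if (!all(is.finite(num)) || !all(is.finite(cfg$stage_effect_sizes))) {
    stop("cohort_config values must all be finite")
  }
  p <- cfg$stage_distribution
  if (length(p) != 6L || any(p < 0)) {
    stop("stage_distribution must be 6 nonnegative probabilities")
  }
  if (abs(sum(p) - 1) > 1e-9) stop("stage_distribution must sum to 1")
  if (any(cfg$control_region_sds <= 0) || cfg$interval_sd_y <= 0) {
    stop("all sds must be strictly positive")
  }
  if (cfg$donation_fraction < 0 || cfg$donation_fraction > 1) {
    stop("donation_fraction must be in [0, 1]")
  }
  regions <- psp_subregions()$subregion
  if (!setequal(names(cfg$control_region_means), regions) ||
      !setequal(names(cfg$control_region_sds), regions) ||
      !setequal(rownames(cfg$stage_effect_sizes), regions)) {
    stop("region names must match psp_subregions()")
  }
  # cumulative pathology: elevation never decreases with stage
  if (any(apply(cfg$stage_effect_sizes, 1, function(r) any(diff(r) < 0)))) {
    stop("stage_effect_sizes rows must be non-decreasing across stages")
  }
  invisible(cfg)
}

#' Generate a seeded synthetic cohort
#'
#' Draws one synthetic cohort under a [cohort_config()]: controls and
#' patients with per-subregion left/right BP_ND values, gray+white-matter
#' fractions, ages, scanner classes, PSPRS scores for patients, and a
#' donation subset with postmortem stage and PET-to-death interval. A patient
#' at true stage s receives the cumulative elevation configured for stage s
#' in every subregion, plus an age slope, a PET/MRI scanner offset, optional
#' subject-level random effect, and i.i.d. Gaussian regional noise. The
#' postmortem stage equals the true stage at scan plus a Poisson progression
#' increment with mean proportional to the interval, capped at VI. Identical
#' config and seed give identical output.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return tibble with one row per subject: `subject_id`, `group`,
#'   `phenotype`, `age_y`, `scanner`, `psprs`, `bp_left_<subregion>`,
#'   `bp_right_<subregion>`, `gmwm_<subregion>`, `true_stage` (0 = none for
#'   controls, 1--6 for patients), `postmortem_stage` and `interval_y`
#'   (`NA` outside the donation subset).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  .validate_cohort_config(config)
  set.seed(seed)
  regions <- psp_subregions()$subregion
  n_c <- config$n_controls
  n_p <- config$n_patients
  if (n_c == 0L) {
    warning("cohort generated with no controls; ",
            "normative w-score models cannot be fitted from it")
  }
  n <- n_c + n_p
  group <- rep(c("control", "patient"), c(n_c, n_p))
  age <- c(rnorm(n_c, config$control_age_mean, config$control_age_sd),
           rnorm(n_p, config$patient_age_mean, config$patient_age_sd))
  age <- pmax(age, 30)
  scanner <- c(
    sample(c("petmr", "petct", "pet"), n_c, replace = TRUE,
           prob = config$scanner_probs_controls),
    sample(c("petmr", "petct", "pet"), n_p, replace = TRUE,
           prob = config$scanner_probs_patients))
  phenotype <- c(rep("control", n_c),
                 sample(c("PSP-RS", "PSP-CBS", "PSP-F", "PSP-OM", "PSP-PGF"),
                        n_p, replace = TRUE,
                        prob = c(35, 2, 2, 2, 1) / 42))
  true_stage <- c(rep(0L, n_c),
                  sample(1:6, n_p, replace = TRUE,
                         prob = config$stage_distribution))
  psprs <- rep(NA_real_, n)
  if (n_p > 0L) {
    mu <- config$psprs_mean +
      config$psprs_stage_coupling * (true_stage[group == "patient"] - 3.5)
    psprs[group == "patient"] <-
      pmin(100, pmax(0, rnorm(n_p, mu, config$psprs_sd)))
  }
  subj_eff <- rnorm(n, 0, config$subject_effect_sd)

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, phenotype = phenotype, age_y = age,
    scanner = scanner, psprs = psprs)

  noise_scale <- ifelse(group == "patient", config$patient_noise_scale, 1)
  for (r in regions) {
    elev <- ifelse(true_stage > 0L,
                   config$stage_effect_sizes[r, pmax(true_stage, 1L)], 0)
    v <- config$control_region_means[[r]] +
      config$age_slope * (age - config$control_age_mean) +
      config$scanner_offset * (scanner == "petmr") +
      elev + subj_eff +
      rnorm(n, 0, config$control_region_sds[[r]] * noise_scale)
    out[[paste0("bp_left_", r)]] <- v + rnorm(n, 0, config$lr_noise_sd)
    out[[paste0("bp_right_", r)]] <- v + rnorm(n, 0, config$lr_noise_sd)
    out[[paste0("gmwm_", r)]] <- runif(n, 0.82, 0.98)
  }

  out$true_stage <- true_stage
  out$postmortem_stage <- NA_integer_
  out$interval_y <- NA_real_
  n_donor <- round(config$donation_fraction * n_p)
  if (n_donor > 0L) {
    donors <- sample(which(group == "patient"), n_donor)
    interval <- pmax(0.1, rnorm(n_donor, config$interval_mean_y,
                                config$interval_sd_y))
    increment <- rpois(n_donor, config$progression_rate * interval)
    out$interval_y[donors] <- interval
    out$postmortem_stage[donors] <-
      pmin(6L, true_stage[donors] + increment)
  }
  out
}

#' Simulate a target time--activity curve under the SRTM forward model
#'
#' Computes the target-region TAC implied by the simplified reference tissue
#' model, `C_T(t) = R1 C_ref(t) + (k2 - R1 k2a) (C_ref (x) exp(-k2a t))`,
#' with the convolution evaluated on a fine internal time grid and averaged
#' over frames, then adds i.i.d. Gaussian frame noise. The delivery term uses
#' the reference frame values directly, so with `R1 = 1`, `bp_nd = 0` the
#' output reproduces the reference exactly.
#'
#' @param params an [srtm_params()] object.
#' @param reference a [tac()] for the reference region.
#' @param noise_sd Gaussian frame-noise SD (same units as activity), >= 0.
#' @param dt fine-grid resolution (minutes) for the convolution.
#' @param region_label label for the simulated curve.
#' @return a [tac()] with the reference's framing scheme.
#' @export
#' @examples
#' ref <- default_reference_curve(90, 20)
#' sim <- simulate_tac(srtm_params(1, 0.1, 0.5), ref, noise_sd = 0)
simulate_tac <- function(params, reference, noise_sd = 0, dt = 0.05,
                         region_label = "target") {
  stopifnot(inherits(params, "srtm_params"), inherits(reference, "tac"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (nrow(reference) == 0L) stop("reference TAC is empty")
  g <- .fine_grid(reference, dt)
  conv <- .conv_exp(g$c, g$dt, params$k2a)
  conv_f <- .frame_average(g$t, conv, reference)
  act <- params$R1 * reference$activity +
    (params$k2 - params$R1 * params$k2a) * conv_f
  if (noise_sd > 0) act <- act + rnorm(length(act), 0, noise_sd)
  tac(reference$frame_start, reference$frame_end, act, region_label)
}

#' Default synthetic reference-region curve
#'
#' A deterministic, smooth uptake--washout curve (gamma-variate shape,
#' peaking around 16 min) framed over `[0, duration_min]` with frame
#' durations that lengthen over the scan, emulating the cerebellar-cortex
#' gray-matter reference of a 90-min dynamic flortaucipir acquisition.
#'
#' @param duration_min total scan duration in minutes (> 0).
#' @param n_frames number of frames (>= 4).
#' @return a [tac()] labelled `cerebellar_cortex_gm`.
#' @export
default_reference_curve <- function(duration_min = 90, n_frames = 20) {
  if (duration_min <= 0) stop("duration_min must be positive")
  if (n_frames < 4L) stop("need at least 4 frames")
  breaks <- duration_min * seq(0, 1, length.out = n_frames + 1)^1.5
  shape <- function(t) (t^2 * exp(-t / 8)) / (16^2 * exp(-2))
  act <- vapply(seq_len(n_frames), function(j) {
    tt <- seq(breaks[j], breaks[j + 1], length.out = 101)
    mean(shape(tt))
  }, numeric(1))
  tac(breaks[-(n_frames + 1)], breaks[-1L], act, "cerebellar_cortex_gm")
}
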