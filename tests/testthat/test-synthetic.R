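test_that("cohort generation is reproducible and matches the configured sizes", {
  cfg <- cohort_config(seed = 5L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 39 + 42)
  expect_equal(sum(a$group == "control"), 39)
  expect_true(all(a$true_stage[a$group == "control"] == 0L))
  expect_true(all(a$true_stage[a$group == "patient"] %in% 1:6))
  # different seed, different draws
  expect_false(identical(generate_cohort(cfg, seed = 6L)$age_y, a$age_y))
})

test_that("the donation subset matches the configured interval distribution", {
  cfg <- cohort_config(seed = 1L)
  coh <- generate_cohort(cfg)
  donors <- !is.na(coh$postmortem_stage)
  expect_equal(sum(donors), round(9 / 42 * 42))
  expect_true(all(coh$group[donors] == "patient"))
  expect_true(all(!is.na(coh$interval_y[donors])))
  expect_true(all(is.na(coh$interval_y[!donors])))
  # sample interval mean within 3 SE of the configured 2.45 y (SD 0.98)
  se <- 0.98 / sqrt(sum(donors))
  expect_lt(abs(mean(coh$interval_y[donors]) - 2.45), 3 * se)
  # postmortem stage never regresses below the stage at scan
  expect_true(all(coh$postmortem_stage[donors] >= coh$true_stage[donors]))
  expect_true(all(coh$postmortem_stage[donors] <= 6L))
})

test_that("null stage effects leave patients distributionally equal to controls", {
  cfg <- cohort_config(n_controls = 800L, n_patients = 800L,
                       stage_effect_sizes = matrix(
                         0, 6, 6, dimnames = dimnames(stage_effect_matrix())),
                       age_slope = 0, scanner_offset = 0,
                       control_age_mean = 65, patient_age_mean = 65,
                       control_age_sd = 7, patient_age_sd = 7, seed = 2L)
  coh <- generate_cohort(cfg)
  for (r in c("globus_pallidus", "middle_frontal")) {
    v <- bilateral_average(coh[[paste0("bp_left_", r)]],
                           coh[[paste0("bp_right_", r)]])
    d <- mean(v[coh$group == "patient"]) - mean(v[coh$group == "control"])
    # difference of two means of 800 draws with sd ~0.1: 4 SE band
    expect_lt(abs(d), 4 * 0.11 * sqrt(2 / 800))
  }
})

test_that("regional elevation is cumulative and non-decreasing in true stage", {
  m <- stage_effect_matrix()
  expect_true(all(apply(m, 1, function(r) all(diff(r) >= 0))))
  # pallidal involvement from stage I; occipital only from stage V
  expect_gt(m["globus_pallidus", "I"], 0)
  expect_equal(m["lingual", "IV"], 0)
  expect_gt(m["lingual", "V"], 0)
  # generated group means follow the configured elevations
  cfg <- cohort_config(n_controls = 0L, n_patients = 1200L,
                       stage_distribution = rep(1 / 6, 6),
                       age_slope = 0, scanner_offset = 0,
                       donation_fraction = 0, seed = 3L)
  coh <- suppressWarnings(generate_cohort(cfg))
  gp <- bilateral_average(coh$bp_left_globus_pallidus,
                          coh$bp_right_globus_pallidus)
  by_stage <- tapply(gp, coh$true_stage, mean)
  expect_lt(by_stage[["1"]], by_stage[["2"]])
  expect_equal(unname(by_stage[["2"]] - by_stage[["1"]]),
               m["globus_pallidus", "II"] - m["globus_pallidus", "I"],
               tolerance = 0.05)
})

test_that("an empty control group is returned with a warning", {
  cfg <- cohort_config(n_controls = 0L, n_patients = 5L, seed = 4L)
  expect_warning(coh <- generate_cohort(cfg), "no controls")
  expect_equal(sum(coh$group == "control"), 0)
  expect_equal(nrow(coh), 5)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(stage_distribution = rep(0.2, 6)), "sum to 1")
  expect_error(cohort_config(stage_distribution = c(-0.1, 0.3, 0.2, 0.2,
                                                    0.2, 0.2)),
               "nonnegative")
  expect_error(cohort_config(donation_fraction = 1.5), "donation_fraction")
  expect_error(cohort_config(interval_sd_y = 0), "positive")
  m <- stage_effect_matrix()
  m["globus_pallidus", "III"] <- 0  # decreasing row violates cumulativity
  expect_error(cohort_config(stage_effect_sizes = m), "non-decreasing")
})

test_that("the default reference curve has the right framing and shape", {
  ref <- default_reference_curve(90, 20)
  expect_s3_class(ref, "tac")
  expect_equal(nrow(ref), 20)
  expect_equal(ref$frame_start[1], 0)
  expect_equal(max(ref$frame_end), 90)
  # contiguous frames
  expect_equal(ref$frame_start[-1], ref$frame_end[-20])
  # uptake then washout, peaking before 30 min
  peak_t <- (ref$frame_start + ref$frame_end)[which.max(ref$activity)] / 2
  expect_lt(peak_t, 30)
  expect_true(all(ref$activity > 0))
  expect_error(default_reference_curve(-1, 20), "positive")
  expect_error(default_reference_curve(90, 3), "4 frames")
})

test_that("noise-free TAC simulation is deterministic, noisy simulation seeded", {
  ref <- ref20()
  p <- srtm_params(1.1, 0.12, 0.4)
  expect_identical(simulate_tac(p, ref, 0), simulate_tac(p, ref, 0))
  set.seed(1); a <- simulate_tac(p, ref, 0.05)
  set.seed(1); b <- simulate_tac(p, ref, 0.05)
  expect_identical(a, b)
  expect_false(identical(a$activity, simulate_tac(p, ref, 0)$activity))
  expect_error(simulate_tac(p, ref, -1), "noise_sd")
})
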