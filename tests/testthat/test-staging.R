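test_that("severity coding follows the tau / 2-tau rule with strict upper bounds", {
  tau <- 0.795
  expect_equal(severity_score(tau, tau), 0L)          # w == tau: absent
  expect_equal(severity_score(0.9, tau), 1L)
  expect_equal(severity_score(1.60, tau), 2L)         # 2*tau = 1.59
  expect_equal(severity_score(2 * tau, tau), 1L)      # w == 2 tau: mild
  expect_equal(severity_score(c(-1, 0.8, 5), tau), c(0L, 1L, 2L))
  expect_error(severity_score(Inf, tau), "non-finite")
  expect_error(severity_score(1, 0), "positive")
})

test_that("composite severity is the maximum over subregions", {
  expect_equal(aggregate_composite(c(1, 0)), 1L)
  expect_equal(aggregate_composite(c(2, 1)), 2L)
  expect_equal(aggregate_composite(c(0, 0)), 0L)
  expect_error(aggregate_composite(integer(0)), "no subregion")
  expect_error(aggregate_composite(3), "0, 1 or 2")
})

test_that("step-1 staging implements the cumulative rules", {
  s <- function(gp, cer, fr, occ) {
    assign_stage_step1(c(GP = gp, CER = cer, FR = fr, OCC = occ))
  }
  expect_equal(s(0, 0, 0, 0)$step1, "no_stage")
  expect_equal(s(1, 0, 0, 0)$step1, "I/II")
  expect_equal(s(1, 1, 0, 0)$step1, "III/IV")
  expect_equal(s(1, 0, 1, 0)$step1, "III/IV")
  expect_equal(s(1, 1, 0, 1)$step1, "V/VI")
  expect_false(s(1, 1, 0, 1)$atypical)
  # no pallidal signal with signal elsewhere violates the sequence
  expect_equal(s(0, 0, 1, 0)$step1, "unclassifiable")
  expect_equal(s(0, 1, 1, 1)$step1, "unclassifiable")
  # occipital involvement skipping frontal/cerebellar: staged but atypical
  atyp <- s(1, 0, 0, 1)
  expect_equal(atyp$step1, "V/VI")
  expect_true(atyp$atypical)
  expect_error(assign_stage_step1(c(GP = 1, CER = 0, FR = 0)), "OCC")
})

test_that("step-2 substaging splits each pair on the defining region's severity", {
  sev <- function(gp, cer, fr, occ) c(GP = gp, CER = cer, FR = fr, OCC = occ)
  expect_equal(assign_substage("I/II", sev(1, 0, 0, 0)), "I")
  expect_equal(assign_substage("I/II", sev(2, 0, 0, 0)), "II")
  expect_equal(assign_substage("III/IV", sev(2, 0, 1, 0)), "III")
  expect_equal(assign_substage("III/IV", sev(1, 2, 1, 0)), "IV")
  expect_equal(assign_substage("V/VI", sev(2, 2, 2, 1)), "V")
  expect_equal(assign_substage("V/VI", sev(2, 2, 2, 2)), "VI")
  expect_equal(assign_substage("no_stage", sev(0, 0, 0, 0)), "no_stage")
  expect_equal(assign_substage("unclassifiable", sev(0, 1, 0, 0)),
               "unclassifiable")
  expect_error(assign_substage("I/II", sev(0, 0, 0, 0)), "pallidal")
})

test_that("all 81 severity vectors map to exactly one coherent outcome", {
  grid <- expand.grid(GP = 0:2, CER = 0:2, FR = 0:2, OCC = 0:2)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    stage_from_severity(unlist(grid[i, ]))
  })
  step1 <- vapply(res, `[[`, character(1), "step1")
  step2 <- vapply(res, `[[`, character(1), "step2")
  expect_equal(length(step2), 81)
  expect_true(all(step1 %in% c("no_stage", "I/II", "III/IV", "V/VI",
                               "unclassifiable")))
  expect_true(all(step2 %in% c("no_stage", "I", "II", "III", "IV", "V",
                               "VI", "unclassifiable")))
  # refinement: substages fall inside their step-1 pair, and only there
  expect_true(all((step2 %in% c("I", "II")) == (step1 == "I/II")))
  expect_true(all((step2 %in% c("III", "IV")) == (step1 == "III/IV")))
  expect_true(all((step2 %in% c("V", "VI")) == (step1 == "V/VI")))
  # unclassifiable exactly when GP absent but another region involved
  expect_equal(step1 == "unclassifiable",
               grid$GP == 0 & (grid$CER > 0 | grid$FR > 0 | grid$OCC > 0))
})

test_that("numeric stage is monotone in every severity coordinate", {
  grid <- expand.grid(GP = 0:2, CER = 0:2, FR = 0:2, OCC = 0:2)
  num <- vapply(seq_len(nrow(grid)), function(i) {
    stage_from_severity(unlist(grid[i, ]))$numeric_stage
  }, numeric(1))
  for (i in seq_len(nrow(grid))) {
    for (reg in names(grid)) {
      if (grid[i, reg] < 2) {
        nxt <- grid[i, ]
        nxt[[reg]] <- nxt[[reg]] + 1
        j <- which(grid$GP == nxt$GP & grid$CER == nxt$CER &
                     grid$FR == nxt$FR & grid$OCC == nxt$OCC)
        if (!is.na(num[i]) && !is.na(num[j])) {
          expect_gte(num[j], num[i])
        }
      }
    }
  }
})

test_that("raising any threshold never increases a subject's stage", {
  coh <- generate_cohort(recovery_config(seed = 19L))
  ws <- build_wscores(coh)
  thr1 <- derive_thresholds(ws$wscores, method = "sd_based", k_sd = 1.2)
  base <- stage_cohort(ws$wscores, thr1)$numeric_stage
  for (r in psp_subregions()$subregion) {
    thr2 <- thr1
    thr2$tau[thr2$region == r] <- thr2$tau[thr2$region == r] * 2
    raised <- stage_cohort(ws$wscores, thr2)$numeric_stage
    ok <- !is.na(base) & !is.na(raised)
    expect_true(all(raised[ok] <= base[ok]))
  }
})

test_that("cohort staging handles forced compositions and missing values", {
  regions <- psp_subregions()$subregion
  thr <- do.call(rbind, lapply(regions, sd_threshold, k_sd = 1))
  mk <- function(w) {
    out <- tibble::tibble(subject_id = sprintf("P%d", seq_len(nrow(w))),
                          group = "patient")
    for (i in seq_along(regions)) out[[paste0("w_", regions[i])]] <- w[, i]
    out
  }
  # all below threshold -> no_stage; GP just above -> stage I
  w <- rbind(rep(0, 6), c(1.5, 0, 0, 0, 0, 0))
  staged <- stage_cohort(mk(w), thr)
  expect_equal(staged$step2, c("no_stage", "I"))
  expect_equal(staged$numeric_stage, c(0, 1))
  # missing dentate cannot change a clear stage IV -> staged anyway
  w_na <- matrix(c(3, 3, NA, 3, 0, 0), 1)
  expect_equal(stage_cohort(mk(w_na), thr)$step2, "IV")
  # missing GP can flip between unclassifiable and staged -> flagged
  w_amb <- matrix(c(NA, 3, 0, 0, 0, 0), 1)
  expect_equal(stage_cohort(mk(w_amb), thr)$step2, "unclassifiable_missing")
  expect_true(is.na(stage_cohort(mk(w_amb), thr)$numeric_stage))
  # step-1-only staging codes pair midpoints
  coarse <- stage_cohort(mk(rbind(c(1.5, 0, 0, 0, 0, 0))), thr,
                         substage = FALSE)
  expect_equal(coarse$step2, "I/II")
  expect_equal(coarse$numeric_stage, 1.5)
})

test_that("true stages are recovered under strong effects and low noise", {
  coh <- generate_cohort(recovery_config(seed = 11L))
  ws <- build_wscores(coh)
  thr <- derive_thresholds(ws$wscores, method = "sd_based", k_sd = 1.645)
  staged <- stage_cohort(ws$wscores, thr)
  pat <- staged$group == "patient"
  truth <- roman_stage(coh$true_stage[match(staged$subject_id[pat],
                                            coh$subject_id)])
  expect_gte(mean(staged$step2[pat] == truth), 0.9)
})
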