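# Shared fixtures for the test suite; everything is generated in code.

ref20 <- function() default_reference_curve(90, 20)

# Cohort with strong stage separation and little noise, for recovery checks.
recovery_config <- function(seed = 11L) {
  cohort_config(n_controls = 100L, n_patients = 60L,
                stage_effect_sizes = stage_effect_matrix(mild = 0.25,
                                                         severe = 0.60),
                patient_noise_scale = 0.2, lr_noise_sd = 0.01,
                subject_effect_sd = 0, seed = seed)
}

# Brute-force argmax over all midpoints using chisq.test as the independent
# association statistic (no continuity correction).
oracle_split <- function(w, g) {
  u <- sort(unique(w))
  mids <- (u[-1L] + u[-length(u)]) / 2
  stat <- vapply(mids, function(m) {
    tab <- table(factor(w <= m, c(TRUE, FALSE)), g)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  }, numeric(1))
  list(split = mids[which.max(stat)], stat = max(stat), mids = mids,
       stats = stat)
}

# Spearman r straight from the rank definition with midranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-step OLS residualization via explicit normal equations, then the
# rank-formula correlation of the residual vectors.
residual_oracle <- function(invivo, postmortem, psprs, interval) {
  X <- cbind(1, psprs, interval)
  res_of <- function(y) y - X %*% solve(t(X) %*% X, t(X) %*% y)
  spearman_oracle(res_of(invivo), res_of(postmortem))
}

roman_stage <- function(k) c("I", "II", "III", "IV", "V", "VI")[k]
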