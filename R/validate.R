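#' One-way ANOVA of clinical severity across stages
#'
#' Fixed-effects one-way ANOVA of PSPRS scores over stage groups, used to
#' ask whether the assigned in vivo stage tracks clinical severity.
#'
#' @param psprs numeric clinical severity scores.
#' @param stages stage labels (numeric codes or factor); `NA` pairs dropped.
#' @return list: `F`, `p`, `df`, `group_means` (named), `group_n`.
#' @export
#' @examples
#' anova_by_stage(c(1, 2, 3, 7, 8, 9), rep(c("I", "II"), each = 3))
anova_by_stage <- function(psprs, stages) {
  keep <- !is.na(psprs) & !is.na(stages)
  psprs <- psprs[keep]
  g <- factor(stages[keep])
  tab <- table(g)
  if (sum(tab >= 2L) < 2L) {
    stop("need at least 2 stage groups with at least 2 members each")
  }
  fit <- lm(psprs ~ g)
  sst <- sum((psprs - mean(psprs))^2)
  if (sum(fit$residuals^2) <= 1e-12 * sst) {
    stop("zero within-group variance: ANOVA F undefined")
  }
  an <- stats::anova(fit)
  gm <- tapply(psprs, g, mean)
  list(F = an["g", "F value"], p = an["g", "Pr(>F)"],
       df = unname(an$Df), group_means = setNames(as.vector(gm), names(gm)),
       group_n = as.vector(tab))
}

#' Spearman agreement between in vivo and postmortem stages
#'
#' Spearman rank correlation with midrank tie handling between two
#' numerically coded stage vectors. The p-value uses exact enumeration for
#' n <= 9 without ties, and the large-sample approximation otherwise.
#'
#' @param invivo,postmortem numeric stage codes; incomplete pairs dropped.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   `NULL` (default) chooses exact for tie-free n <= 9.
#' @return list: `r`, `p`, `n`.
#' @export
#' @examples
#' spearman_agreement(c(1, 2, 3, 4), c(2, 2, 4, 6))
spearman_agreement <- function(invivo, postmortem, exact = NULL) {
  keep <- !is.na(invivo) & !is.na(postmortem)
  x <- as.numeric(invivo[keep])
  y <- as.numeric(postmortem[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in a stage vector: correlation undefined")
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (is.null(exact)) exact <- n <= 9L && !ties
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Residualized stage agreement after removing severity and interval
#'
#' Regresses each numerically coded staging variable (in vivo and
#' postmortem) on clinical severity (PSPRS) and the PET-to-death interval by
#' ordinary least squares, then returns the Spearman correlation of the two
#' residual vectors. The linear residualization of ordinal codes mirrors the
#' original analysis procedure exactly, coarse as it is statistically.
#'
#' @param invivo,postmortem numeric stage codes.
#' @param psprs clinical severity scores.
#' @param interval_y PET-to-death intervals (years).
#' @return list: `r`, `p`, `n`.
#' @export
residualized_correlation <- function(invivo, postmortem, psprs, interval_y) {
  keep <- !is.na(invivo) & !is.na(postmortem) & !is.na(psprs) &
    !is.na(interval_y)
  n <- sum(keep)
  if (n < 5L) stop("need at least 5 complete cases")
  x <- cbind(psprs = psprs[keep], interval = interval_y[keep])
  if (qr(cbind(1, x))$rank < 3L) stop("collinear covariates")
  r1 <- lm(invivo[keep] ~ x)$residuals
  r2 <- lm(postmortem[keep] ~ x)$residuals
  if (sd(r1) < 1e-10 || sd(r2) < 1e-10) {
    stop("a staging variable is fully explained by the covariates; ",
         "residual correlation undefined")
  }
  spearman_agreement(r1, r2, exact = FALSE)
}

#' Proportion of cases with in vivo stage at or below the postmortem stage
#'
#' Because pathology progresses between scan and death, the in vivo stage is
#' expected to be less than or equal to the postmortem stage in most donors;
#' this reports that fraction over complete pairs.
#'
#' @param invivo,postmortem numeric stage codes.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' proportion_le(c(2, 4, 4), c(2, 3, 6))  # 2/3
proportion_le <- function(invivo, postmortem) {
  keep <- !is.na(invivo) & !is.na(postmortem)
  if (!any(keep)) stop("no complete in vivo / postmortem pairs")
  mean(invivo[keep] <= postmortem[keep])
}

#' Assemble the validation report for a staged cohort
#'
#' Computes the full set of validation statistics: the ANOVA of PSPRS by
#' step-2 stage over patients, and over the donation subset the Spearman
#' agreement of in vivo with postmortem stage, its residualized version
#' (removing PSPRS and interval), and the proportion with in vivo <=
#' postmortem. Statistics whose preconditions fail (e.g. too few donors)
#' are reported as `NA` with a warning rather than aborting the pipeline.
#'
#' @param staging staging table from [stage_cohort()].
#' @param cohort cohort table with `subject_id`, `psprs`,
#'   `postmortem_stage`, `interval_y`.
#' @return list of class `agreement_report`: `n_pairs`, `spearman_r`,
#'   `spearman_p`, `residual_r`, `residual_p`, `prop_le`, `anova_F`,
#'   `anova_p`, `group_means`.
#' @export
agreement_report <- function(staging, cohort) {
  idx <- match(staging$subject_id, cohort$subject_id)
  if (any(is.na(idx))) stop("staging and cohort tables do not align")
  psprs <- cohort$psprs[idx]
  pm <- cohort$postmortem_stage[idx]
  interval <- cohort$interval_y[idx]
  patient <- staging$group == "patient"
  try_stat <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NULL
  })
  an <- try_stat(anova_by_stage(psprs[patient],
                                staging$numeric_stage[patient]))
  pairs <- patient & !is.na(pm) & !is.na(staging$numeric_stage)
  sp <- try_stat(spearman_agreement(staging$numeric_stage[pairs], pm[pairs]))
  rc <- try_stat(residualized_correlation(staging$numeric_stage[pairs],
                                          pm[pairs], psprs[pairs],
                                          interval[pairs]))
  pl <- try_stat(proportion_le(staging$numeric_stage[pairs], pm[pairs]))
  structure(list(
    n_pairs = sum(pairs),
    spearman_r = if (is.null(sp)) NA_real_ else sp$r,
    spearman_p = if (is.null(sp)) NA_real_ else sp$p,
    residual_r = if (is.null(rc)) NA_real_ else rc$r,
    residual_p = if (is.null(rc)) NA_real_ else rc$p,
    prop_le = if (is.null(pl)) NA_real_ else pl,
    anova_F = if (is.null(an)) NA_real_ else an$F,
    anova_p = if (is.null(an)) NA_real_ else an$p,
    group_means = if (is.null(an)) NULL else an$group_means),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  in vivo vs postmortem pairs: %d\n", x$n_pairs))
  cat(sprintf("  Spearman r = %.3f (p = %.3g)\n", x$spearman_r, x$spearman_p))
  cat(sprintf("  residualized r = %.3f (p = %.3g)\n",
              x$residual_r, x$residual_p))
  cat(sprintf("  in vivo <= postmortem: %.2f\n", x$prop_le))
  cat(sprintf("  PSPRS ANOVA: F = %.3f (p = %.3g)\n", x$anova_F, x$anova_p))
  invisible(x)
}
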