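#' Fit a per-region normative w-score model on controls
#'
#' Ordinary least squares of control bilateral BP_ND on age and a PET/MRI
#' scanner indicator. The residual SD uses the `n - p` denominator (`p` =
#' number of fitted coefficients); set `df_method = "n-1"` for the
#' alternative convention. If only one scanner class is present among the
#' controls the scanner term is dropped with a warning.
#'
#' @param values control regional BP_ND (bilateral, post-PVC).
#' @param age ages in years.
#' @param petmr logical/0-1 indicator: PET/MRI scanner vs non-PET/MRI.
#' @param region region label stored with the model.
#' @param min_controls minimum number of controls required (default 10).
#' @param df_method `"n-p"` (default) or `"n-1"` for the residual-SD
#'   denominator.
#' @return list of class `wscore_model`: `region`, `coefficients`
#'   (`intercept`, `age`, `petmr`), `residual_sd`, `n_controls`.
#' @export
#' @examples
#' set.seed(1)
#' age <- runif(40, 50, 85)
#' v <- 0.5 + 0.002 * age + rnorm(40, 0, 0.1)
#' m <- fit_wscore_model(v, age, rbinom(40, 1, 0.5), "globus_pallidus")
#' compute_wscore(m, v[1], age[1], 0)
fit_wscore_model <- function(values, age, petmr, region = "region",
                             min_controls = 10L,
                             df_method = c("n-p", "n-1")) {
  df_method <- match.arg(df_method)
  n <- length(values)
  stopifnot(length(age) == n, length(petmr) == n)
  petmr <- as.numeric(petmr)
  if (n < min_controls) {
    stop("need at least ", min_controls, " controls to fit region '",
         region, "' (got ", n, ")")
  }
  use_scanner <- length(unique(petmr)) > 1L
  if (!use_scanner) {
    warning("only one scanner class among controls for region '", region,
            "'; dropping the scanner term")
  }
  X <- if (use_scanner) cbind(intercept = 1, age = age, petmr = petmr)
       else cbind(intercept = 1, age = age)
  p <- ncol(X)
  if (n < p + 2L) stop("fewer controls than coefficients + 2")
  if (qr(X)$rank < p) stop("rank-deficient normative design")
  fit <- .lm.fit(X, values)
  res <- fit$residuals
  denom <- if (df_method == "n-p") n - p else n - 1L
  residual_sd <- sqrt(sum(res^2) / denom)
  if (residual_sd < 1e-10 * max(1, abs(mean(values)))) {
    stop("degenerate normative model for region '", region,
         "': residual SD is zero")
  }
  co <- fit$coefficients
  names(co) <- colnames(X)
  if (!use_scanner) co <- c(co, petmr = 0)
  structure(list(region = region, coefficients = co,
                 residual_sd = residual_sd, n_controls = n,
                 df_method = df_method),
            class = "wscore_model")
}

#' @export
print.wscore_model <- function(x, ...) {
  cat(sprintf(
    "<wscore_model> %s: mu = %.4f + %.5f*age + %.4f*petmr, residual sd %.4f (n = %d)\n",
    x$region, x$coefficients["intercept"], x$coefficients["age"],
    x$coefficients["petmr"], x$residual_sd, x$n_controls))
  invisible(x)
}

#' Covariate-adjusted w-score
#'
#' A w-score is a z-score referenced to the control cohort after regression
#' adjustment for covariates: `w = (observed - predicted) / residual_sd`,
#' where the prediction comes from the control normative model.
#'
#' @param model a [fit_wscore_model()] result.
#' @param value observed regional BP_ND (vectorized).
#' @param age age in years (vectorized).
#' @param petmr PET/MRI indicator (vectorized).
#' @return numeric w-score(s).
#' @export
compute_wscore <- function(model, value, age, petmr) {
  stopifnot(inherits(model, "wscore_model"))
  if (any(is.na(age)) || any(is.na(petmr))) {
    stop("missing covariate (age or scanner)")
  }
  if (model$residual_sd <= 0) stop("residual_sd must be positive")
  co <- model$coefficients
  pred <- co["intercept"] + co["age"] * age + co["petmr"] * as.numeric(petmr)
  unname((value - pred) / model$residual_sd)
}

#' Fit normative models and compute the cohort w-score table
#'
#' Convenience wrapper over the full cohort table: averages left/right BP_ND
#' bilaterally for every subregion, fits one normative model per subregion on
#' the controls, and returns w-scores for every subject.
#'
#' @param cohort a cohort tibble as produced by [generate_cohort()] (columns
#'   `bp_left_<r>`, `bp_right_<r>`, `age_y`, `scanner`, `group`).
#' @param min_controls forwarded to [fit_wscore_model()].
#' @return list with `models` (named list of `wscore_model`) and `wscores`, a
#'   tibble `subject_id`, `group`, `psprs`, and one `w_<subregion>` column
#'   per subregion.
#' @export
build_wscores <- function(cohort, min_controls = 10L) {
  regions <- psp_subregions()$subregion
  need <- c(paste0("bp_left_", regions), paste0("bp_right_", regions),
            "age_y", "scanner", "group", "subject_id")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  is_control <- cohort$group == "control"
  if (sum(is_control) < min_controls) {
    stop("need at least ", min_controls, " controls to fit w-score models")
  }
  petmr <- as.numeric(cohort$scanner == "petmr")
  wtab <- tibble::tibble(subject_id = cohort$subject_id,
                         group = cohort$group,
                         psprs = if ("psprs" %in% names(cohort))
                           cohort$psprs else NA_real_)
  models <- list()
  for (r in regions) {
    bil <- bilateral_average(cohort[[paste0("bp_left_", r)]],
                             cohort[[paste0("bp_right_", r)]])
    m <- fit_wscore_model(bil[is_control], cohort$age_y[is_control],
                          petmr[is_control], region = r,
                          min_controls = min_controls)
    models[[r]] <- m
    wtab[[paste0("w_", r)]] <- compute_wscore(m, bil, cohort$age_y, petmr)
  }
  list(models = models, wscores = wtab)
}
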