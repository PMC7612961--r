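#' Three-level regional pathology severity from a w-score
#'
#' Codes a regional w-score against its abnormality threshold `tau`:
#' 0 (absent) when `w <= tau`; 1 (mild/moderate) when `tau < w <= 2 tau`;
#' 2 (moderate/severe) when `w > 2 tau`. Both comparisons are strict on the
#' upper side, so `w == tau` is absent and `w == 2 tau` is mild/moderate.
#'
#' @param w numeric w-score(s); must be finite (NA passes through as NA).
#' @param tau positive threshold (scalar or vector matching `w`).
#' @return integer severity in `{0, 1, 2}` (or `NA`).
#' @export
#' @examples
#' severity_score(c(0.5, 0.9, 1.7), tau = 0.795)  # 0 1 2
severity_score <- function(w, tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be positive")
  if (any(is.nan(w) | is.infinite(w))) stop("non-finite w-score")
  out <- ifelse(w > 2 * tau, 2L, ifelse(w > tau, 1L, 0L))
  as.integer(out)
}

#' Aggregate subregion severities into a composite region
#'
#' A composite region (cerebellum = white matter + dentate; occipital =
#' lingual + cuneus) is as severe as its most severe subregion: pathology in
#' either subregion constitutes involvement of the composite.
#'
#' @param severities vector of subregion severities in `{0, 1, 2}`.
#' @return maximum severity.
#' @export
#' @examples
#' aggregate_composite(c(1, 0))  # 1
aggregate_composite <- function(severities) {
  severities <- severities[!is.na(severities)]
  if (length(severities) == 0L) stop("no subregion severities to aggregate")
  if (!all(severities %in% 0:2)) stop("severities must be 0, 1 or 2")
  as.integer(max(severities))
}

#' Step-1 coarse stage from regional presence/absence
#'
#' Applies the cumulative staging rules to the binary presence pattern over
#' the four composites: no region involved gives `no_stage`; involvement
#' without the globus pallidus violates the cumulative sequence and is
#' `unclassifiable`; pallidal involvement alone is stage I/II; adding
#' frontal or cerebellar involvement (occipital spared) is III/IV; adding
#' occipital involvement is V/VI. Occipital involvement without frontal or
#' cerebellar involvement is staged V/VI at the highest supported level but
#' flagged atypical, since it departs from the canonical sequence.
#'
#' @param presence named logical/0-1 vector with entries `GP`, `CER`, `FR`,
#'   `OCC`.
#' @return list with `step1` (one of `no_stage`, `I/II`, `III/IV`, `V/VI`,
#'   `unclassifiable`) and `atypical` (logical).
#' @export
#' @examples
#' assign_stage_step1(c(GP = 1, CER = 0, FR = 0, OCC = 0))  # I/II
assign_stage_step1 <- function(presence) {
  comps <- psp_composites()
  if (!all(comps %in% names(presence))) {
    stop("presence must be named with: ", paste(comps, collapse = ", "))
  }
  pr <- setNames(as.logical(presence[comps]), comps)
  if (any(is.na(pr))) stop("presence values must be 0/1")
  gp <- pr["GP"]; cer <- pr["CER"]; fr <- pr["FR"]; occ <- pr["OCC"]
  if (!any(pr)) return(list(step1 = "no_stage", atypical = FALSE))
  if (!gp) return(list(step1 = "unclassifiable", atypical = FALSE))
  if (!cer && !fr && !occ) return(list(step1 = "I/II", atypical = FALSE))
  if (!occ) return(list(step1 = "III/IV", atypical = FALSE))
  # GP and OCC involved; atypical when the intermediate regions are spared
  list(step1 = "V/VI", atypical = unname(!(cer || fr)))
}

#' Step-2 substage within a step-1 stage
#'
#' Refines the coarse stage using the 3-level severity of the stage-defining
#' composite: I/II splits on pallidal severity (1 = stage I, 2 = stage II);
#' III/IV on the maximum of frontal and cerebellar severity (1 = III,
#' 2 = IV); V/VI on occipital severity (1 = V, 2 = VI). `no_stage` and
#' `unclassifiable` pass through unchanged.
#'
#' @param step1 step-1 label.
#' @param severity named severity vector over `GP`, `CER`, `FR`, `OCC`.
#' @return step-2 label.
#' @export
#' @examples
#' assign_substage("I/II", c(GP = 2, CER = 0, FR = 0, OCC = 0))  # "II"
assign_substage <- function(step1, severity) {
  comps <- psp_composites()
  if (!all(comps %in% names(severity))) {
    stop("severity must be named with: ", paste(comps, collapse = ", "))
  }
  sev <- as.integer(severity[comps])
  names(sev) <- comps
  if (step1 %in% c("no_stage", "unclassifiable", "unclassifiable_missing")) {
    return(step1)
  }
  switch(step1,
    "I/II" = {
      if (sev["GP"] == 0L) stop("step1 = I/II requires pallidal involvement")
      if (sev["GP"] == 1L) "I" else "II"
    },
    "III/IV" = {
      fc <- max(sev["FR"], sev["CER"])
      if (fc == 0L) stop("step1 = III/IV requires frontal or cerebellar involvement")
      if (fc == 1L) "III" else "IV"
    },
    "V/VI" = {
      if (sev["OCC"] == 0L) stop("step1 = V/VI requires occipital involvement")
      if (sev["OCC"] == 1L) "V" else "VI"
    },
    stop("unknown step1 label: ", step1))
}

#' Full stage assignment from composite severities
#'
#' Runs step 1 (binary presence, cumulative rules) and step 2 (3-level
#' severity refinement) for one severity vector.
#'
#' @param severity named severity vector over `GP`, `CER`, `FR`, `OCC`,
#'   values in `{0, 1, 2}`.
#' @param substage apply step-2 refinement (default `TRUE`); when `FALSE`
#'   the numeric stage uses the step-1 pair midpoints.
#' @return list: `step1`, `step2`, `atypical`, `numeric_stage`.
#' @export
#' @examples
#' stage_from_severity(c(GP = 2, CER = 1, FR = 0, OCC = 0))
stage_from_severity <- function(severity, substage = TRUE) {
  s1 <- assign_stage_step1(severity > 0)
  step2 <- if (substage) assign_substage(s1$step1, severity) else s1$step1
  list(step1 = s1$step1, step2 = step2, atypical = s1$atypical,
       numeric_stage = stage_numeric(if (substage) step2 else s1$step1))
}

# Stage a single subject's subregion severities, handling missing values:
# the subject is staged only if the missing subregions cannot change the
# outcome (identical assignment with all NAs at severity 0 and at severity
# 2); otherwise flagged unclassifiable_missing.
.stage_subject <- function(sev_sub, sub2comp, substage = TRUE) {
  comp_of <- function(fill) {
    s <- sev_sub
    s[is.na(s)] <- fill
    vapply(psp_composites(), function(cc) {
      aggregate_composite(s[sub2comp == cc])
    }, integer(1))
  }
  if (!any(is.na(sev_sub))) {
    return(stage_from_severity(comp_of(0L), substage))
  }
  lo <- stage_from_severity(comp_of(0L), substage)
  hi <- stage_from_severity(comp_of(2L), substage)
  if (identical(lo$step2, hi$step2) && identical(lo$step1, hi$step1)) {
    lo$atypical <- lo$atypical || hi$atypical
    return(lo)
  }
  list(step1 = "unclassifiable_missing", step2 = "unclassifiable_missing",
       atypical = FALSE, numeric_stage = NA_real_)
}

#' Stage every subject of a cohort
#'
#' Applies severity scoring, composite aggregation, and the two-step staging
#' automaton to every subject in a w-score table. Controls are staged by the
#' same rules as patients. Subjects with missing w-scores are staged only
#' when the missing region cannot change the outcome; otherwise they are
#' flagged `unclassifiable_missing` rather than dropped.
#'
#' @param wscores w-score table from [build_wscores()] (columns
#'   `subject_id`, `group`, `w_<subregion>`).
#' @param thresholds a `threshold_set` from [derive_thresholds()] (or any
#'   tibble with `region`, `tau` covering all subregions).
#' @param substage apply step-2 refinement (default `TRUE`).
#' @return tibble: `subject_id`, `group`, per-composite w-score
#'   (`w_GP`, ...; maximum over subregions), per-composite severity
#'   (`sev_GP`, ...), `step1`, `step2`, `atypical`, `numeric_stage`.
#' @export
stage_cohort <- function(wscores, thresholds, substage = TRUE) {
  map <- psp_subregions()
  missing_reg <- setdiff(map$subregion, thresholds$region)
  if (length(missing_reg) > 0L) {
    stop("threshold set lacks region(s): ",
         paste(missing_reg, collapse = ", "))
  }
  missing_cols <- setdiff(paste0("w_", map$subregion), names(wscores))
  if (length(missing_cols) > 0L) {
    stop("w-score table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tau <- setNames(thresholds$tau, thresholds$region)[map$subregion]
  n <- nrow(wscores)
  wmat <- sapply(map$subregion, function(r) wscores[[paste0("w_", r)]])
  wmat <- matrix(wmat, nrow = n,
                 dimnames = list(NULL, map$subregion))
  out <- tibble::tibble(subject_id = wscores$subject_id,
                        group = wscores$group)
  comps <- psp_composites()
  for (cc in comps) {
    sub <- map$subregion[map$composite == cc]
    out[[paste0("w_", cc)]] <- apply(wmat[, sub, drop = FALSE], 1, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  }
  res <- lapply(seq_len(n), function(i) {
    sev <- severity_score(wmat[i, ], tau)
    names(sev) <- map$subregion
    .stage_subject(sev, map$composite, substage)
  })
  for (cc in comps) {
    sub <- map$subregion[map$composite == cc]
    out[[paste0("sev_", cc)]] <- vapply(seq_len(n), function(i) {
      sv <- severity_score(wmat[i, sub], tau[sub])
      if (all(is.na(sv))) NA_integer_ else as.integer(max(sv, na.rm = TRUE))
    }, integer(1))
  }
  out$step1 <- vapply(res, `[[`, character(1), "step1")
  out$step2 <- vapply(res, `[[`, character(1), "step2")
  out$atypical <- vapply(res, `[[`, logical(1), "atypical")
  out$numeric_stage <- vapply(res, `[[`, numeric(1), "numeric_stage")
  out
}
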