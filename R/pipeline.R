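#' Run the full in vivo staging pipeline on a cohort table
#'
#' Executes the analysis end-to-end: bilateral averaging and per-region
#' normative w-score models fitted on controls, per-region abnormality
#' thresholds (data-driven with fallback, or SD-based), the two-step staging
#' automaton over all subjects, and the validation statistics. All
#' intermediate artifacts are returned; if `output_dir` is given they are
#' also written to disk (w-score CSV, threshold JSON, staging CSV, report
#' JSON, provenance JSON).
#'
#' @param cohort cohort tibble (see [generate_cohort()] / [read_cohort()]).
#' @param threshold_method `"data_driven"` or `"sd_based"`.
#' @param alpha,n_perm,k_sd threshold settings (see [derive_thresholds()]).
#' @param seed integer seed for the permutation tests (required for the
#'   data-driven method).
#' @param substage apply step-2 substaging.
#' @param min_controls minimum controls for the normative models.
#' @param output_dir optional directory for the written artifacts.
#' @return list of class `psp_pipeline`: `models`, `wscores`, `thresholds`,
#'   `staging`, `report`, `settings`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' res <- run_pipeline(cohort, threshold_method = "sd_based", k_sd = 2)
#' table(res$staging$step2[res$staging$group == "patient"])
run_pipeline <- function(cohort,
                         threshold_method = c("data_driven", "sd_based"),
                         alpha = 0.05, n_perm = 9999L, k_sd = 2,
                         seed = NULL, substage = TRUE, min_controls = 10L,
                         output_dir = NULL) {
  threshold_method <- match.arg(threshold_method)
  ws <- build_wscores(cohort, min_controls = min_controls)
  thr <- derive_thresholds(ws$wscores, method = threshold_method,
                           alpha = alpha, n_perm = n_perm, k_sd = k_sd,
                           seed = seed)
  staged <- stage_cohort(ws$wscores, thr, substage = substage)
  report <- agreement_report(staged, cohort)
  flagged <- staged$subject_id[staged$atypical |
                                 grepl("unclassifiable", staged$step1)]
  if (length(flagged) > 0L) {
    message("atypical or unclassifiable subjects: ",
            paste(flagged, collapse = ", "))
  }
  settings <- list(threshold_method = threshold_method, alpha = alpha,
                   n_perm = as.integer(n_perm), k_sd = k_sd, seed = seed,
                   substage = substage, min_controls = as.integer(min_controls))
  out <- structure(list(models = ws$models, wscores = ws$wscores,
                        thresholds = thr, staging = staged, report = report,
                        settings = settings),
                   class = "psp_pipeline")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_wscore_table(ws$wscores, file.path(output_dir, "wscores.csv"))
    write_thresholds(thr, file.path(output_dir, "thresholds.json"))
    write_staging(staged, file.path(output_dir, "staging.csv"))
    jsonlite::write_json(unclass(report)[
      c("n_pairs", "spearman_r", "spearman_p", "residual_r", "residual_p",
        "prop_le", "anova_F", "anova_p")],
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(settings, file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' @export
print.psp_pipeline <- function(x, ...) {
  cat("<psp_pipeline>\n")
  cat("  thresholds:\n")
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("    %-16s tau = %.3f (%s)\n", x$thresholds$region[i],
                x$thresholds$tau[i], x$thresholds$source[i]))
  }
  pt <- x$staging$group == "patient"
  cat("  patient step-2 stages: ",
      paste(sprintf("%s=%d", names(table(x$staging$step2[pt])),
                    as.vector(table(x$staging$step2[pt]))), collapse = ", "),
      "\n")
  print(x$report)
  invisible(x)
}

# ---- readers / writers ----------------------------------------------------

#' Cohort, w-score, threshold and staging table input/output
#'
#' Plain-text round-trip helpers for the pipeline's artifacts: cohort and
#' staging tables and the w-score matrix as CSV, threshold sets as JSON, and
#' TACs as CSV with `frame_start_min`, `frame_end_min`, `activity`,
#' `region_label` columns. `read_cohort_config()` accepts a YAML or JSON
#' file whose keys mirror the [cohort_config()] arguments
#' (`stage_effect_sizes` as a list of per-region rows).
#'
#' @param x object to write.
#' @param path file path.
#' @return readers return tibbles (or a [tac()], or a `cohort_config`);
#'   writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age_y", "scanner")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname pipeline_io
#' @export
write_wscore_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_wscore_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @export
write_thresholds <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_thresholds <- function(path) {
  df <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(df)
  class(out) <- c("threshold_set", class(out))
  out
}

#' @rdname pipeline_io
#' @export
write_staging <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_staging <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$atypical <- as.logical(df$atypical)
  tibble::as_tibble(df)
}

#' @rdname pipeline_io
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  out <- data.frame(frame_start_min = x$frame_start,
                    frame_end_min = x$frame_end,
                    activity = x$activity,
                    region_label = x$region_label)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tac <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tac(df$frame_start_min, df$frame_end_min, df$activity,
      df$region_label[1L])
}

#' @rdname pipeline_io
#' @export
read_cohort_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  for (nm in c("stage_distribution", "control_region_means",
               "control_region_sds", "scanner_probs_controls",
               "scanner_probs_patients")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$stage_effect_sizes)) {
    m <- do.call(rbind, lapply(cfg$stage_effect_sizes, unlist))
    colnames(m) <- c("I", "II", "III", "IV", "V", "VI")
    cfg$stage_effect_sizes <- m
  }
  do.call(cohort_config, cfg)
}
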