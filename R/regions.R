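#' Staging regions for PSP tau pathology
#'
#' The in vivo staging scheme evaluates four composite regions, mirroring the
#' cumulative postmortem progression of PSP tau pathology: globus pallidus
#' (GP), cerebellum (CER; white matter and dentate nucleus), middle frontal
#' gyrus (FR), and occipital lobe (OCC; lingual gyrus and cuneus). Thresholds
#' and w-scores are computed per subregion; composites aggregate subregion
#' severities by maximum. The striatum and subthalamic nucleus are not part of
#' the scheme because of off-target flortaucipir binding.
#'
#' @return `psp_subregions()`: a tibble with columns `subregion` and
#'   `composite`. `psp_composites()`: character vector of the four composite
#'   labels in progression order.
#' @export
#' @examples
#' psp_subregions()
psp_subregions <- function() {
  tibble::tibble(
    subregion = c("globus_pallidus", "cerebellar_wm", "dentate",
                  "middle_frontal", "lingual", "cuneus"),
    composite = c("GP", "CER", "CER", "FR", "OCC", "OCC")
  )
}

#' @rdname psp_subregions
#' @export
psp_composites <- function() c("GP", "CER", "FR", "OCC")

# Ordered outcome labels for the two staging steps.
.step1_levels <- c("no_stage", "I/II", "III/IV", "V/VI",
                   "unclassifiable", "unclassifiable_missing")
.step2_levels <- c("no_stage", "I", "II", "III", "IV", "V", "VI",
                   "unclassifiable", "unclassifiable_missing")

#' Numeric coding of stage labels
#'
#' Maps step-2 substages I--VI to 1--6 and `no_stage` to 0; `unclassifiable`
#' (and `unclassifiable_missing`) become `NA` and are excluded from numeric
#' analyses. When only step-1 pairs are available they are coded at the pair
#' midpoint (I/II = 1.5, III/IV = 3.5, V/VI = 5.5).
#'
#' @param stage character vector of stage labels (step-1 or step-2).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' stage_numeric(c("no_stage", "II", "IV", "V/VI", "unclassifiable"))
stage_numeric <- function(stage) {
  map <- c(no_stage = 0, I = 1, II = 2, III = 3, IV = 4, V = 5, VI = 6,
           `I/II` = 1.5, `III/IV` = 3.5, `V/VI` = 5.5,
           unclassifiable = NA_real_, unclassifiable_missing = NA_real_)
  bad <- setdiff(unique(stage[!is.na(stage)]), names(map))
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  unname(map[as.character(stage)])
}
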