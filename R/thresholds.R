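# One-sided standard-normal critical value at P = 0.05, to the three decimals
# used as the fixed fallback cut point when no data-driven split is found.
W_FALLBACK <- 1.645

# chi-square statistics of the 2x2 (group x side-of-split) tables for all
# candidate split positions, given 0/1 group labels in w-sorted order.
# split_idx[j] = number of observations at or below split j.
.split_chisq <- function(g_sorted, split_idx, n, n1) {
  a <- cumsum(g_sorted)[split_idx]          # group-1 count left of split
  left <- split_idx
  num <- (a * n - left * n1)^2 * n          # n*(ad - bc)^2 simplified
  den <- n1 * (n - n1) * left * (n - left)
  num / den
}

#' Data-driven abnormality threshold by binary recursive partitioning
#'
#' Finds the single best split of the pooled control + patient w-scores, in
#' the manner of a conditional-inference tree's first split: candidate cut
#' points are midpoints between consecutive sorted unique w-scores; the split
#' maximizing the chi-square association between group and side-of-split is
#' selected; and global significance is assessed by permuting group labels
#' and comparing the maximal statistic (max-T correction over all candidate
#' splits). The split is returned as the threshold only when the permutation
#' p-value falls below `alpha`; otherwise the search reports no threshold and
#' callers fall back to the fixed critical value (see
#' [resolve_threshold()]). Only the first split is used even if deeper splits
#' would be significant. Ties in the statistic resolve to the smallest
#' midpoint.
#'
#' @param w numeric w-scores, pooled over both groups.
#' @param group group labels (two levels; logical, factor or character).
#' @param alpha significance level of the permutation stop rule.
#' @param n_perm number of label permutations (>= 999).
#' @param seed integer seed for the permutations.
#' @return list of class `threshold_search`: `threshold` (`NA` if not
#'   significant), `candidate` (the argmax midpoint regardless of
#'   significance), `statistic`, `p_value`, `n_perm`.
#' @export
#' @examples
#' set.seed(7)
#' w <- c(rnorm(40, 0), rnorm(40, 4))
#' g <- rep(c("control", "patient"), each = 40)
#' find_threshold(w, g, n_perm = 999, seed = 7)$threshold
find_threshold <- function(w, group, alpha = 0.05, n_perm = 9999L,
                           seed = NULL) {
  stopifnot(is.numeric(w), length(w) == length(group))
  if (n_perm < 999L) stop("n_perm must be >= 999")
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) stop("both groups must be present")
  if (any(!is.finite(w))) stop("w-scores must be finite")
  ord <- order(w)
  ws <- w[ord]
  gs <- g[ord]
  n <- length(ws)
  n1 <- sum(gs)
  split_idx <- which(diff(ws) > 0)
  if (length(split_idx) == 0L) stop("all w-scores identical: no candidate split")
  obs <- .split_chisq(gs, split_idx, n, n1)
  best <- which(obs >= max(obs) - 1e-12)[1L]  # ties: smallest midpoint
  stat <- obs[best]
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    gp <- sample(gs)
    if (max(.split_chisq(gp, split_idx, n, n1)) >= stat - 1e-12) {
      count <- count + 1L
    }
  }
  p <- (1 + count) / (n_perm + 1)
  candidate <- (ws[split_idx[best]] + ws[split_idx[best] + 1L]) / 2
  structure(list(threshold = if (p < alpha) candidate else NA_real_,
                 candidate = candidate, statistic = stat, p_value = p,
                 n_perm = as.integer(n_perm)),
            class = "threshold_search")
}

#' Resolve a region's threshold: data-driven value or fixed fallback
#'
#' If the data-driven search produced a threshold it is used as is;
#' otherwise the region receives the fixed w-score critical value 1.645
#' (the one-sided standard-normal quantile at P = 0.05), as was done for the
#' occipital lobe where no significant split exists.
#'
#' @param region region label.
#' @param data_driven numeric threshold, or `NULL`/`NA` when the search
#'   found none. A `threshold_search` object is also accepted.
#' @param p_value optional permutation p-value to record.
#' @return one-row tibble: `region`, `tau`, `source`
#'   (`data_driven`/`fallback`), `p_value`, `k_sd` (`NA` here).
#' @export
#' @examples
#' resolve_threshold("globus_pallidus", 0.795)
#' resolve_threshold("lingual", NULL)  # fallback 1.645
resolve_threshold <- function(region, data_driven = NULL,
                              p_value = NA_real_) {
  if (inherits(data_driven, "threshold_search")) {
    p_value <- data_driven$p_value
    data_driven <- data_driven$threshold
  }
  if (!is.null(data_driven) && length(data_driven) == 1L &&
      is.finite(data_driven)) {
    tibble::tibble(region = region, tau = as.numeric(data_driven),
                   source = "data_driven", p_value = p_value,
                   k_sd = NA_real_)
  } else {
    tibble::tibble(region = region, tau = W_FALLBACK, source = "fallback",
                   p_value = p_value, k_sd = NA_real_)
  }
}

#' SD-multiple abnormality threshold
#'
#' The alternative thresholding scheme marks a region abnormal when its value
#' exceeds the control mean by a preselected number of control SDs. On the
#' w-score scale this is simply `w > k_sd` (with an intercept-only covariate
#' model, control mean + k SD corresponds exactly to w = k; with covariates,
#' w already measures SD units from the covariate-adjusted control mean), so
#' the threshold equals the multiplier itself.
#'
#' @param region region label.
#' @param k_sd positive SD multiplier (default 2).
#' @return one-row tibble: `region`, `tau = k_sd`, `source = "sd_based"`,
#'   `p_value` (`NA`), `k_sd`.
#' @export
#' @examples
#' sd_threshold("globus_pallidus", 2)
sd_threshold <- function(region, k_sd = 2) {
  if (!is.finite(k_sd) || k_sd <= 0) stop("k_sd must be positive")
  tibble::tibble(region = region, tau = as.numeric(k_sd),
                 source = "sd_based", p_value = NA_real_,
                 k_sd = as.numeric(k_sd))
}

#' Derive per-region abnormality thresholds for a cohort
#'
#' Runs the configured thresholding method over every subregion of the
#' w-score table: `data_driven` runs [find_threshold()] on patients +
#' controls per region and falls back to 1.645 where no significant split is
#' found; `sd_based` applies a fixed SD multiplier to every region.
#'
#' @param wscores w-score table from [build_wscores()] (columns `w_<region>`
#'   and `group`).
#' @param method `"data_driven"` or `"sd_based"`.
#' @param alpha,n_perm permutation-test settings for the data-driven search.
#' @param k_sd SD multiplier for the `sd_based` method.
#' @param seed integer seed (required for `data_driven`). Per-region seeds
#'   are derived deterministically from it.
#' @return tibble of class `threshold_set`, one row per subregion, columns
#'   `region`, `tau`, `source`, `p_value`, `k_sd`.
#' @export
derive_thresholds <- function(wscores,
                              method = c("data_driven", "sd_based"),
                              alpha = 0.05, n_perm = 9999L, k_sd = 2,
                              seed = NULL) {
  method <- match.arg(method)
  regions <- psp_subregions()$subregion
  missing_cols <- setdiff(paste0("w_", regions), names(wscores))
  if (length(missing_cols) > 0L) {
    stop("w-score table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (method == "sd_based") {
    out <- do.call(rbind, lapply(regions, sd_threshold, k_sd = k_sd))
  } else {
    if (is.null(seed)) stop("a seed is required for the data-driven search")
    out <- do.call(rbind, lapply(seq_along(regions), function(i) {
      r <- regions[i]
      search <- find_threshold(wscores[[paste0("w_", r)]], wscores$group,
                               alpha = alpha, n_perm = n_perm,
                               seed = seed + i)
      resolve_threshold(r, search)
    }))
  }
  class(out) <- c("threshold_set", class(out))
  out
}
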