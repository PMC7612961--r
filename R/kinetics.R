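#' CSF partial-volume correction of a regional PET value
#'
#' Corrects regional PET data for dilution by cerebrospinal fluid by dividing
#' the regional value by the mean regional gray-plus-white-matter tissue
#' fraction. Applied to every frame of a regional TAC before kinetic
#' modeling; the fraction is treated as frame-constant.
#'
#' @param value numeric regional PET quantity (a frame value or a vector of
#'   them).
#' @param gmwm_fraction tissue fraction in (0, 1]; scalar or vector matching
#'   `value`.
#' @return `value / gmwm_fraction`.
#' @export
#' @examples
#' pvc_correct(0.8, 0.8)  # 1.0
pvc_correct <- function(value, gmwm_fraction) {
  if (any(!is.finite(gmwm_fraction)) || any(gmwm_fraction <= 0) ||
      any(gmwm_fraction > 1)) {
    stop("gmwm_fraction must lie in (0, 1]")
  }
  value / gmwm_fraction
}

#' Basis grid configuration for the SRTM fit
#'
#' The basis-function SRTM fit searches the apparent target washout rate
#' `k2a` over a fixed logarithmic grid and solves a linear least-squares
#' subproblem at each grid point. The default grid, 100 points over
#' 0.006--0.6 / min, spans physiological washout for flortaucipir-class
#' tracers.
#'
#' @param k2a_min,k2a_max grid bounds (1/min), `0 < k2a_min < k2a_max`.
#' @param n_basis number of grid points (>= 10).
#' @return list of class `basis_config` with a precomputed `grid`.
#' @export
basis_config <- function(k2a_min = 0.006, k2a_max = 0.6, n_basis = 100L) {
  if (!(k2a_min > 0 && k2a_min < k2a_max)) {
    stop("need 0 < k2a_min < k2a_max")
  }
  if (n_basis < 10L) stop("n_basis must be >= 10")
  structure(list(k2a_min = k2a_min, k2a_max = k2a_max,
                 n_basis = as.integer(n_basis),
                 grid = exp(seq(log(k2a_min), log(k2a_max),
                                length.out = n_basis))),
            class = "basis_config")
}

#' Fit the simplified reference tissue model by basis functions
#'
#' For each `k2a` on the configured grid, forms the basis
#' `B(t) = C_ref (x) exp(-k2a t)` (fine-grid convolution, frame-averaged)
#' and solves the linear least-squares problem
#' `C_T ~ theta1 C_ref + theta2 B`. The grid point minimizing the residual
#' sum of squares is selected; parameters follow as `R1 = theta1`,
#' `k2 = theta2 + theta1 k2a`, `bp_nd = k2 / k2a - 1`. Ties in RSS resolve
#' to the smallest `k2a`. `theta2` may be negative (bp_nd below 0 occurs
#' with real tracers); a fit implying `bp_nd <= -1` is rejected.
#'
#' @param target,reference [tac()] objects sharing an identical framing
#'   scheme with at least 4 frames.
#' @param basis a [basis_config()].
#' @param dt fine-grid resolution (minutes) for the convolution.
#' @param weights optional per-frame weights (e.g. frame durations); default
#'   unweighted.
#' @return list of class `srtm_fit`: `R1`, `k2`, `k2a`, `bp_nd`, `rss`,
#'   `basis_index`, and the `rss_grid` across all basis functions.
#' @export
#' @examples
#' ref <- default_reference_curve(90, 20)
#' fit_srtm_basis(ref, ref)$bp_nd  # identity target: ~0
fit_srtm_basis <- function(target, reference, basis = basis_config(),
                           dt = 0.05, weights = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"),
            inherits(basis, "basis_config"))
  if (!.same_framing(target, reference)) {
    stop("target and reference must share an identical framing scheme")
  }
  if (nrow(target) < 4L) stop("need at least 4 frames")
  if (max(abs(reference$activity)) < 1e-12) {
    stop("degenerate reference TAC (constant zero)")
  }
  w <- if (is.null(weights)) rep(1, nrow(target)) else weights
  stopifnot(length(w) == nrow(target), all(w > 0))
  sw <- sqrt(w)
  y <- target$activity * sw
  g <- .fine_grid(reference, dt)
  rss_grid <- numeric(basis$n_basis)
  theta <- matrix(NA_real_, basis$n_basis, 2L)
  for (i in seq_len(basis$n_basis)) {
    b <- .frame_average(g$t, .conv_exp(g$c, g$dt, basis$grid[i]), reference)
    X <- cbind(reference$activity, b) * sw
    fit <- .lm.fit(X, y)
    theta[i, ] <- fit$coefficients
    rss_grid[i] <- sum(fit$residuals^2)
  }
  if (!all(is.finite(rss_grid))) stop("non-finite RSS on basis grid")
  best <- which.min(rss_grid)
  k2a <- basis$grid[best]
  R1 <- theta[best, 1L]
  k2 <- theta[best, 2L] + R1 * k2a
  bp_nd <- k2 / k2a - 1
  if (!is.finite(bp_nd) || bp_nd <= -1) {
    stop("failed fit: implied bp_nd <= -1")
  }
  structure(list(R1 = R1, k2 = k2, k2a = k2a, bp_nd = bp_nd,
                 rss = rss_grid[best], basis_index = best,
                 rss_grid = rss_grid),
            class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf(
    "<srtm_fit> R1 = %.4f, k2 = %.4f /min, k2a = %.4f /min, BP_ND = %.4f (rss %.3g)\n",
    x$R1, x$k2, x$k2a, x$bp_nd, x$rss))
  invisible(x)
}

#' Bilateral averaging of left/right regional values
#'
#' Left and right regional BP_ND values are averaged; if exactly one side is
#' missing the other is returned with a warning. Vectorized.
#'
#' @param left,right numeric vectors (may contain `NA`).
#' @return numeric vector of bilateral means.
#' @export
#' @examples
#' bilateral_average(0.4, 0.6)  # 0.5
bilateral_average <- function(left, right) {
  stopifnot(length(left) == length(right))
  if (any(is.na(left) & is.na(right))) {
    stop("both hemispheric values missing")
  }
  one_sided <- xor(is.na(left), is.na(right))
  if (any(one_sided)) {
    warning(sum(one_sided),
            " value(s) available on one hemisphere only; using that side")
  }
  out <- (left + right) / 2
  out[one_sided] <- ifelse(is.na(left[one_sided]),
                           right[one_sided], left[one_sided])
  out
}
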