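#' Construct a framed time--activity curve
#'
#' A TAC holds the framed radioactivity signal for one region of a dynamic
#' PET acquisition: frame start/end times in minutes and one activity value
#' per frame (frame average, arbitrary but consistent concentration units).
#'
#' @param frame_start,frame_end numeric vectors of frame boundaries (minutes);
#'   frames must be contiguous-or-gapped, non-overlapping and strictly
#'   increasing, with `frame_end > frame_start`.
#' @param activity numeric vector of frame-averaged activity, same length.
#' @param region_label single character label for the region.
#' @return A tibble of class `tac` with columns `frame_start`, `frame_end`,
#'   `activity`, `region_label`.
#' @export
#' @examples
#' tac(c(0, 1, 2), c(1, 2, 4), c(5, 9, 7), "cerebellar_cortex_gm")
tac <- function(frame_start, frame_end, activity, region_label = "region") {
  n <- length(frame_start)
  stopifnot(length(frame_end) == n, length(activity) == n, n >= 1L,
            is.character(region_label), length(region_label) == 1L)
  if (!all(is.finite(frame_start)) || !all(is.finite(frame_end)) ||
      !all(is.finite(activity))) {
    stop("TAC frame times and activities must be finite")
  }
  if (any(frame_end <= frame_start)) {
    stop("every frame must satisfy frame_end > frame_start")
  }
  if (n > 1L && (any(diff(frame_start) <= 0) ||
                 any(frame_start[-1L] < frame_end[-n] - 1e-9))) {
    stop("frames must be strictly increasing and non-overlapping")
  }
  out <- tibble::tibble(frame_start = as.numeric(frame_start),
                        frame_end = as.numeric(frame_end),
                        activity = as.numeric(activity),
                        region_label = region_label)
  class(out) <- c("tac", class(out))
  out
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region '%s': %d frames over [%.2f, %.2f] min\n",
              x$region_label[1L], nrow(x), min(x$frame_start),
              max(x$frame_end)))
  NextMethod()
}

.tac_midpoints <- function(x) (x$frame_start + x$frame_end) / 2

.same_framing <- function(a, b, tol = 1e-8) {
  nrow(a) == nrow(b) &&
    max(abs(a$frame_start - b$frame_start)) < tol &&
    max(abs(a$frame_end - b$frame_end)) < tol
}

# Fine internal time grid spanning the acquisition, and the reference signal
# interpolated onto it (linear through frame midpoints, anchored at 0 at t=0).
.fine_grid <- function(reference, dt) {
  t_max <- max(reference$frame_end)
  t_grid <- seq(0, t_max, by = dt)
  mids <- .tac_midpoints(reference)
  c_grid <- approx(x = c(0, mids), y = c(0, reference$activity),
                   xout = t_grid, rule = 2)$y
  list(t = t_grid, c = c_grid, dt = dt)
}

# Convolution y(t) = int_0^t c(s) exp(-k2a (t - s)) ds on a uniform grid,
# via the trapezoidal recurrence y_i = e y_{i-1} + dt/2 (c_i + e c_{i-1}),
# e = exp(-k2a dt). Exact for piecewise-linear-in-quadrature inputs; O(n).
.conv_exp <- function(c_grid, dt, k2a) {
  n <- length(c_grid)
  e <- exp(-k2a * dt)
  x <- (dt / 2) * (c_grid + e * c(0, c_grid[-n]))
  x[1L] <- 0
  as.numeric(filter(x, e, method = "recursive"))
}

# Average fine-grid values over each frame interval.
.frame_average <- function(t_grid, values, frames) {
  vapply(seq_len(nrow(frames)), function(j) {
    sel <- t_grid >= frames$frame_start[j] - 1e-12 &
      t_grid <= frames$frame_end[j] + 1e-12
    mean(values[sel])
  }, numeric(1))
}

#' SRTM kinetic parameters
#'
#' Parameter set of the simplified reference tissue model (SRTM): `R1`, the
#' target-to-reference delivery ratio; `k2`, the reference-region efflux rate
#' (1/min); and `bp_nd`, the nondisplaceable binding potential. The apparent
#' target washout rate `k2a = k2 / (1 + bp_nd)` is derived.
#'
#' @param R1 positive delivery ratio (unitless).
#' @param k2 positive efflux rate (1/min).
#' @param bp_nd binding potential, must exceed -1.
#' @return list of class `srtm_params` with fields `R1`, `k2`, `bp_nd`, `k2a`.
#' @export
#' @examples
#' srtm_params(R1 = 1, k2 = 0.1, bp_nd = 0.5)
srtm_params <- function(R1, k2, bp_nd) {
  stopifnot(is.finite(R1), is.finite(k2), is.finite(bp_nd))
  if (R1 <= 0) stop("R1 must be positive")
  if (k2 <= 0) stop("k2 must be positive")
  if (bp_nd <= -1) stop("bp_nd must exceed -1")
  structure(list(R1 = R1, k2 = k2, bp_nd = bp_nd, k2a = k2 / (1 + bp_nd)),
            class = "srtm_params")
}
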