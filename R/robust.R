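#' Origin-constrained robust regression slope
#'
#' Fits `y = b * x` (no intercept) by iteratively reweighted least squares
#' with Tukey bisquare (biweight) weights: starting from the ordinary
#' origin-constrained least-squares slope, residuals are scaled by
#' MAD/0.6745 and weighted by `(1 - u^2)^2` for `|u| < 1` (zero beyond),
#' with tuning constant `c = 4.685`. Iteration stops when the slope changes
#' by less than `tol` or after `max_iter` sweeps. When the residual MAD is
#' zero (an exact linear fit, or y identically zero) the unweighted
#' origin-constrained least-squares slope is returned.
#'
#' @param x instructed-finger peak forces (N); at least 3 values, some > 0.
#' @param y uninstructed-finger peak forces (N), same length.
#' @param c_tuning bisquare tuning constant (default 4.685, the standard
#'   95%-efficiency value).
#' @param max_iter,tol iteration cap and convergence tolerance on the slope.
#' @return The slope in N per N.
#' @export
robust_origin_slope <- function(x, y, c_tuning = 4.685,
                                max_iter = 50L, tol = 1e-8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points for a robust slope")
  if (all(x <= 0)) stop("all instructed forces are <= 0")

  ols <- sum(x * y) / sum(x * x)
  # one reweighted least-squares sweep; NA signals an exact fit (MAD 0,
  # fall back to plain least squares) or total rejection (keep b)
  sweep1 <- function(b) {
    r <- y - b * x
    s <- stats::mad(r, constant = 1 / 0.6745)  # MAD of residuals / 0.6745
    if (s == 0) return(NA_real_)
    u <- r / (c_tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    denom <- sum(w * x * x)
    if (denom == 0) return(NaN)
    sum(w * x * y) / denom
  }
  b <- ols
  for (i in seq_len(max_iter)) {
    b_new <- sweep1(b)
    if (is.na(b_new) && !is.nan(b_new)) return(ols)
    if (is.nan(b_new)) return(b)  # every point rejected; keep current slope
    if (abs(b_new - b) < tol * max(1, abs(b))) return(b_new)
    b <- b_new
  }
  # the scale re-estimate can trap the iteration in a cycle orbiting the
  # fixed point; locate the nearby root of g(b) - b by expanding a bracket
  # around the last iterate and bisecting
  h <- function(b) {
    v <- sweep1(b)
    if (is.na(v)) return(0)
    v - b
  }
  delta <- max(1e-6, 1e-4 * abs(b))
  while (delta < max(1, abs(b))) {
    lo <- b - delta; hi <- b + delta
    if (h(lo) * h(hi) < 0) {
      for (i in 1:100) {
        mid <- (lo + hi) / 2
        if (h(lo) * h(mid) <= 0) hi <- mid else lo <- mid
        if (hi - lo < tol * max(1, abs(mid))) break
      }
      return((lo + hi) / 2)
    }
    delta <- delta * 2
  }
  b
}

#' Log-transform a coupling slope
#'
#' Natural log of the slope, floored at `1e-4` N/N so non-positive slopes
#' (possible for uninstructed fingers that drift into extension) stay
#' finite; the floor is far below any physiologically observed coupling.
#'
#' @param slope slope in N/N.
#' @param floor lower bound applied before taking the log.
#' @return `log(max(slope, floor))`.
#' @export
log_slope <- function(slope, floor = 1e-4) {
  log(pmax(slope, floor))
}
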