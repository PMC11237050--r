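# Slope patterns: 5 x 5 matrices of log-slopes, rows = instructed finger,
# columns = uninstructed finger. Enslaving excludes the diagonal (20 valid
# cells per hand); mirroring uses all 25 cells per direction.

new_slope_pattern <- function(kind, context, cells, slopes, valid, n_points) {
  dimnames(cells) <- dimnames(slopes) <- dimnames(valid) <-
    dimnames(n_points) <- list(instructed = FINGERS, uninstructed = FINGERS)
  structure(list(kind = kind, context = context, cells = cells,
                 slopes = slopes, valid = valid, n_points = n_points),
            class = "slope_pattern")
}

#' @export
print.slope_pattern <- function(x, digits = 3, ...) {
  cat(sprintf("<slope_pattern> %s, context %s: %d valid cells\n",
              x$kind, x$context, sum(x$valid)))
  m <- round(x$cells, digits)
  m[!x$valid] <- NA
  print(m)
  invisible(x)
}

# Shared worker: regress each uninstructed channel's peaks on the
# instructed finger's own peaks, pooled over the three target levels.
fit_pattern <- function(peaks, kind, instructed_hand, passive_hand) {
  cells <- slopes <- matrix(NA_real_, 5, 5)
  valid <- matrix(FALSE, 5, 5)
  n_points <- matrix(0L, 5, 5)
  for (i in seq_along(FINGERS)) {
    fi <- FINGERS[i]
    sub <- peaks[peaks$instructed_hand == instructed_hand &
                   peaks$instructed_finger == fi, , drop = FALSE]
    x <- sub[[paste0("peak_", instructed_hand, "_", fi)]]
    use <- which(x > 0)
    for (j in seq_along(FINGERS)) {
      if (kind == "enslaving" && i == j) next
      y <- sub[[paste0("peak_", passive_hand, "_", FINGERS[j])]]
      n_points[i, j] <- length(use)
      if (length(use) < 3) {
        warning(sprintf(
          "%s %s->%s (%s): only %d usable trial(s); cell marked invalid",
          kind, fi, FINGERS[j], instructed_hand, length(use)))
        next
      }
      sl <- robust_origin_slope(x[use], y[use])
      slopes[i, j] <- sl
      cells[i, j] <- log_slope(sl)
      valid[i, j] <- TRUE
    }
  }
  context <- if (kind == "enslaving") instructed_hand
             else paste0(instructed_hand, "->", passive_hand)
  new_slope_pattern(kind, context, cells, slopes, valid, n_points)
}

#' Estimate a hand's enslaving pattern
#'
#' For every instructed finger `i` and same-hand uninstructed finger
#' `j != i`, regresses the peak enslaved force on the peak instructed force
#' (origin-constrained bisquare IRLS, three target levels pooled) and
#' log-transforms the slope. A complete session yields 20 valid cells; a
#' pair with fewer than 3 usable trials is marked invalid with a warning.
#'
#' @param peaks a [build_peak_table()] result.
#' @param hand instructed hand, `"L"` or `"R"`.
#' @return A `slope_pattern` (kind `"enslaving"`).
#' @export
enslaving_pattern <- function(peaks, hand = c("R", "L")) {
  hand <- match.arg(hand)
  fit_pattern(peaks, "enslaving", hand, hand)
}

#' Estimate a mirroring pattern
#'
#' As [enslaving_pattern()], but the uninstructed fingers are the five
#' fingers of the passive (contralateral) hand, giving 25 valid cells per
#' direction.
#'
#' @param peaks a [build_peak_table()] result.
#' @param active_hand the instructed hand.
#' @return A `slope_pattern` (kind `"mirroring"`, context e.g. `"R->L"`).
#' @export
mirroring_pattern <- function(peaks, active_hand = c("R", "L")) {
  active_hand <- match.arg(active_hand)
  fit_pattern(peaks, "mirroring", active_hand, other_hand(active_hand))
}

#' Overall pattern strength
#'
#' Arithmetic mean of the valid cells' log-slopes, together with its
#' back-transform `exp(mean)` -- the geometric mean of the slopes -- as a
#' readable N-per-N summary. Set `arithmetic = TRUE` to obtain the plain
#' arithmetic mean of the raw slopes instead.
#'
#' @param pattern a `slope_pattern`.
#' @param arithmetic if `TRUE`, also average raw slopes arithmetically.
#' @return A list with `mean_log_slope`, `strength` (back-transformed,
#'   N/N), `n_cells`, and optionally `arithmetic_mean`.
#' @export
mean_pattern_strength <- function(pattern, arithmetic = FALSE) {
  v <- pattern$cells[pattern$valid]
  if (length(v) == 0) stop("pattern has no valid cells")
  out <- list(mean_log_slope = mean(v), strength = exp(mean(v)),
              n_cells = length(v))
  if (arithmetic) out$arithmetic_mean <- mean(pattern$slopes[pattern$valid])
  out
}

# valid-cell values of a pattern as a named vector (row_col order, fixed)
pattern_cells <- function(pattern) {
  idx <- which(pattern$valid)
  v <- pattern$cells[idx]
  rn <- rownames(pattern$valid)[row(pattern$valid)[idx]]
  cn <- colnames(pattern$valid)[col(pattern$valid)[idx]]
  names(v) <- paste0(rn, "_", cn)
  v
}
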