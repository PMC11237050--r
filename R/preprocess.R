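#' Baseline-correct a trial's force trace
#'
#' Subtracts each channel's resting baseline -- the mean force over the
#' final 200 ms of the preparation phase (the window just before the go
#' cue) -- from the whole trace. If fewer pre-cue samples are available the
#' window is truncated with a warning.
#'
#' @param trial a [force_trial()].
#' @param window_s baseline window length in seconds (default 0.2).
#' @return The trial with corrected forces and a `baseline` element holding
#'   the per-channel baseline estimates (N).
#' @export
baseline_correct <- function(trial, window_s = 0.2) {
  n_pre <- trial$go_cue - 1L
  if (n_pre < 1L) stop("trial has no samples before the go cue")
  win <- round(window_s * trial$sample_rate)
  if (n_pre < win) {
    warning(sprintf(
      "baseline window truncated to %d samples (< %d) for %s block %d trial %d",
      n_pre, win, trial$subject_id, trial$block, trial$trial))
    win <- n_pre
  }
  idx <- (n_pre - win + 1L):n_pre
  baseline <- colMeans(trial$forces[idx, , drop = FALSE])
  trial$forces <- sweep(trial$forces, 2L, baseline)
  trial$baseline <- baseline
  trial
}

#' Extract per-channel peak forces from one trial
#'
#' Baseline-corrects the trace (unless already corrected) and takes, per
#' channel, the maximum signed force over the response window (go cue to
#' trial end). Flexion is positive; the signed maximum is used rather than
#' the absolute value, so weak extension dips on uninstructed fingers
#' register as near-zero coupling (the log floor handles them downstream).
#' The instructed peak is compared with the target zone (target +/- 25%)
#' when the subject's MVC is supplied.
#'
#' @param trial a [force_trial()].
#' @param mvc optional 10-vector of per-finger maximum voluntary forces (N)
#'   used to set the target-zone flag.
#' @return A one-row data frame (a peak record): design columns, `in_zone`,
#'   then `peak_<channel>` and `base_<channel>` columns.
#' @export
extract_peaks <- function(trial, mvc = NULL) {
  if (is.null(trial$baseline)) trial <- baseline_correct(trial)
  if (trial$go_cue > trial$trial_end) stop("empty response window")
  win <- trial$go_cue:trial$trial_end
  peaks <- apply(trial$forces[win, , drop = FALSE], 2L, max)
  chan <- channel_index(trial$instructed_hand, trial$instructed_finger)
  in_zone <- NA
  if (!is.null(mvc)) {
    target <- trial$target_level * mvc[chan]
    in_zone <- peaks[chan] >= 0.75 * target && peaks[chan] <= 1.25 * target
  }
  rec <- data.frame(
    subject_id = trial$subject_id, block = trial$block, trial = trial$trial,
    instructed_hand = trial$instructed_hand,
    instructed_finger = trial$instructed_finger,
    target_level = trial$target_level, in_zone = in_zone,
    stringsAsFactors = FALSE)
  rec[paste0("peak_", channel_names())] <- as.list(unname(peaks))
  rec[paste0("base_", channel_names())] <- as.list(unname(trial$baseline))
  rec
}

#' Build a subject's peak table
#'
#' One peak record per trial, ordered by (block, trial). Trials that miss
#' the target zone are flagged (`in_zone`) but never excluded.
#'
#' @param subject a [subject_record()].
#' @return A data frame of class `peak_table`.
#' @export
build_peak_table <- function(subject) {
  if (length(subject$trials) == 0) {
    pt <- extract_peaks(simulate_stub_trial())[0, ]
  } else {
    recs <- lapply(subject$trials, extract_peaks, mvc = subject$mvc)
    pt <- do.call(rbind, recs)
    pt <- pt[order(pt$block, pt$trial), , drop = FALSE]
    rownames(pt) <- NULL
  }
  class(pt) <- c("peak_table", "data.frame")
  pt
}

# minimal trial used only to type an empty peak table
simulate_stub_trial <- function() {
  force_trial("stub", 1, 1, "R", "D2", 0.5,
              matrix(0, 60, 10), go_cue = 45, trial_end = 60)
}
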