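#' Construct a single force trial
#'
#' A trial holds the 10-channel fingertip force trace of one instructed
#' single-finger press, sampled at 200 Hz, together with its design metadata
#' and phase marks. Channels follow the canonical order
#' `L_D1..L_D5, R_D1..R_D5` (see [channel_names()]).
#'
#' @param subject_id subject identifier.
#' @param block block number (>= 1).
#' @param trial trial number within the block (>= 1).
#' @param instructed_hand `"L"` or `"R"`.
#' @param instructed_finger `"D1".."D5"` (thumb to little finger).
#' @param target_level instructed force as a fraction of that finger's
#'   maximum voluntary contraction; one of 0.25, 0.50, 0.75.
#' @param forces numeric matrix, samples x 10 channels, in newtons.
#' @param go_cue sample index (1-based) of the go cue, i.e. the first
#'   response sample; samples before it are the preparation phase.
#' @param trial_end sample index of the last response sample (end of the
#'   hold phase); any later samples are the release.
#' @param sample_rate sampling rate in Hz; the acquisition standard is 200.
#' @return An object of class `force_trial`.
#' @export
force_trial <- function(subject_id, block, trial, instructed_hand,
                        instructed_finger, target_level, forces,
                        go_cue, trial_end, sample_rate = 200) {
  forces <- as.matrix(forces)
  colnames(forces) <- channel_names()
  x <- structure(
    list(subject_id = as.character(subject_id),
         block = as.integer(block), trial = as.integer(trial),
         instructed_hand = instructed_hand,
         instructed_finger = instructed_finger,
         target_level = target_level,
         sample_rate = sample_rate,
         forces = forces,
         go_cue = as.integer(go_cue), trial_end = as.integer(trial_end)),
    class = "force_trial")
  x
}

#' Validate a force trial against its invariants
#'
#' Checks the trial-level invariants: 200 Hz sampling, forces within the
#' transducer range (0-25 N nominal; small negative values are allowed for
#' sensor noise, floor -1 N), ordered phase marks, legal design labels.
#' Returns a character vector of issues -- empty when the trial is
#' well-formed -- rather than raising, so loaders can collect problems.
#'
#' @param trial a [force_trial()].
#' @return character vector of issue descriptions (possibly empty).
#' @export
validate_trial <- function(trial) {
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)
  if (!identical(as.numeric(trial$sample_rate), 200)) {
    add(sprintf("sample_rate: expected 200 Hz, got %s", trial$sample_rate))
  }
  f <- trial$forces
  if (!is.matrix(f) || ncol(f) != 10) {
    add("forces: must be a samples x 10 matrix")
  } else {
    if (any(!is.finite(f))) add("forces: non-finite values present")
    rng <- range(f[is.finite(f)])
    if (length(rng) == 2 && (rng[1] < -1 || rng[2] > 25)) {
      add(sprintf(
        "forces: value(s) outside transducer range [-1, 25] N (range %.3f..%.3f)",
        rng[1], rng[2]))
    }
  }
  n <- nrow(trial$forces)
  if (!(trial$go_cue >= 1 && trial$go_cue < trial$trial_end &&
        trial$trial_end <= n)) {
    add(sprintf(
      "phase_marks: need 1 <= go_cue (%d) < trial_end (%d) <= n_samples (%d)",
      trial$go_cue, trial$trial_end, n))
  }
  if (!trial$instructed_hand %in% HANDS) {
    add(sprintf("instructed_hand: '%s' not in {L, R}", trial$instructed_hand))
  }
  if (!trial$instructed_finger %in% FINGERS) {
    add(sprintf("instructed_finger: '%s' not in {D1..D5}",
                trial$instructed_finger))
  }
  if (!isTRUE(all.equal(trial$target_level, 0.25)) &&
      !isTRUE(all.equal(trial$target_level, 0.50)) &&
      !isTRUE(all.equal(trial$target_level, 0.75))) {
    add(sprintf("target_level: %s not in {0.25, 0.50, 0.75}",
                format(trial$target_level)))
  }
  if (trial$block < 1) add("block: must be >= 1")
  if (trial$trial < 1) add("trial: must be >= 1")
  issues
}

#' @export
print.force_trial <- function(x, ...) {
  cat(sprintf(
    "<force_trial> %s block %d trial %d: %s-%s @ %.0f%% MVC, %d samples @ %g Hz\n",
    x$subject_id, x$block, x$trial, x$instructed_hand, x$instructed_finger,
    100 * x$target_level, nrow(x$forces), x$sample_rate))
  invisible(x)
}
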