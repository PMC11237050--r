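# On-disk cohort format
#
# A cohort directory holds `subjects.json` (the manifest) plus one tidy
# long-format trace CSV per subject, one row per sample:
#   block,trial,instructed_hand,instructed_finger,target_level,phase,
#   time_s,L_D1..L_D5,R_D1..R_D5
# `phase` is prep/press/release and encodes the phase marks (go cue = first
# press sample, trial end = last press sample). Forces are written with 17
# significant digits so a write -> read round trip is bit-exact.

TRACE_COLS <- c("block", "trial", "instructed_hand", "instructed_finger",
                "target_level", "phase", "time_s", channel_names())

#' Write a cohort to disk
#'
#' Writes `subjects.json` and one `<subject_id>_traces.csv` per subject
#' under `out_dir` (created if needed). Row order is deterministic:
#' subjects in cohort order, trials by (block, trial), samples by time.
#'
#' @param x a [cohort()].
#' @param out_dir output directory.
#' @return The manifest path, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(x, out_dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  entries <- lapply(x$subjects, function(s) {
    trace_file <- paste0(s$subject_id, "_traces.csv")
    write_trace_csv(s, file.path(out_dir, trace_file))
    list(subject_id = s$subject_id, group = s$group,
         handedness = s$handedness, mvc = as.numeric(s$mvc),
         symptom_map = as.list(s$symptom_map),
         severity = s$severity, duration_years = s$duration_years,
         age = s$age, sample_rate = 200, trace_file = trace_file)
  })
  manifest <- list(provenance = x$provenance, subjects = entries)
  manifest_path <- file.path(out_dir, "subjects.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null",
                       na = "null")
  invisible(manifest_path)
}

write_trace_csv <- function(subject, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(TRACE_COLS, collapse = ","), con)
  for (tr in subject$trials) {
    n <- nrow(tr$forces)
    phase <- rep("release", n)
    phase[seq_len(tr$go_cue - 1L)] <- "prep"
    phase[tr$go_cue:tr$trial_end] <- "press"
    time_s <- (seq_len(n) - 1L) / tr$sample_rate
    num <- cbind(time_s, tr$forces)
    numtxt <- apply(num, 2L, function(col) sprintf("%.17g", col))
    if (n == 1L) numtxt <- matrix(numtxt, nrow = 1L)
    lead <- sprintf("%d,%d,%s,%s,%s,%s", tr$block, tr$trial,
                    tr$instructed_hand, tr$instructed_finger,
                    sprintf("%.17g", tr$target_level), phase)
    writeLines(paste(lead, apply(numtxt, 1L, paste, collapse = ","),
                     sep = ","), con)
  }
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Loads `subjects.json` and every referenced trace CSV, reconstructs
#' [force_trial()] objects (trials sorted by block then trial; sample order
#' is recovered from `time_s`, so row-permuted CSVs load identically) and
#' validates every trial. A missing trace file raises a load error naming
#' the file; an invariant violation raises a validation error naming the
#' subject, trial and field.
#'
#' @param manifest_path path to `subjects.json`.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  m <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  subjects <- lapply(m$subjects, function(e) {
    trace_path <- file.path(base, e$trace_file)
    if (!file.exists(trace_path)) {
      stop("trace file not found for subject ", e$subject_id, ": ",
           trace_path)
    }
    trials <- read_trace_csv(trace_path, e$subject_id,
                             sample_rate = e$sample_rate %||% 200)
    for (tr in trials) {
      issues <- validate_trial(tr)
      if (length(issues)) {
        stop("validation failed for subject ", e$subject_id, ", block ",
             tr$block, ", trial ", tr$trial, ": ",
             paste(issues, collapse = "; "))
      }
    }
    subject_record(
      subject_id = e$subject_id, group = e$group, handedness = e$handedness,
      mvc = unlist(e$mvc), symptom_map = unlist(e$symptom_map) %||% character(),
      trials = trials,
      severity = e$severity %||% NA_real_,
      duration_years = e$duration_years %||% NA_real_,
      age = e$age %||% NA_real_)
  })
  cohort(subjects, provenance = m$provenance %||% manifest_path)
}

read_trace_csv <- function(path, subject_id, sample_rate = 200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACE_COLS, names(df))
  if (length(missing_cols)) {
    stop("trace file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  key <- interaction(df$block, df$trial, drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    press <- which(d$phase == "press")
    force_trial(
      subject_id = subject_id, block = d$block[1], trial = d$trial[1],
      instructed_hand = d$instructed_hand[1],
      instructed_finger = d$instructed_finger[1],
      target_level = d$target_level[1],
      forces = as.matrix(d[, channel_names()]),
      go_cue = press[1], trial_end = press[length(press)],
      sample_rate = sample_rate)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
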