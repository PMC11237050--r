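#' Construct a subject record
#'
#' A subject bundles group membership, handedness, per-finger maximum
#' voluntary contraction (MVC), the clinical symptom map and all force
#' trials. Controls must have an empty symptom map. A complete session is
#' 10 blocks x 30 trials (3 target levels x 10 fingers) but partial designs
#' are accepted; downstream operations decide their own minimum-data rules.
#'
#' @param subject_id unique identifier.
#' @param group `"patient"` or `"control"`.
#' @param handedness `"L"` or `"R"`.
#' @param mvc numeric vector of 10 per-finger maximum voluntary forces (N),
#'   in canonical channel order; all must be positive.
#' @param symptom_map character vector of symptomatic-finger codes such as
#'   `"R-D3"` (see [parse_symptom_map()]); empty for controls.
#' @param trials list of [force_trial()] objects.
#' @param severity optional Tubiana-Chamagne score (0-5).
#' @param duration_years,age optional clinical covariates.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, handedness, mvc,
                           symptom_map = character(), trials = list(),
                           severity = NA_real_, duration_years = NA_real_,
                           age = NA_real_) {
  group <- match.arg(group, c("patient", "control"))
  handedness <- match.arg(handedness, HANDS)
  mvc <- as.numeric(mvc)
  if (length(mvc) != 10 || any(!is.finite(mvc)) || any(mvc <= 0)) {
    stop("subject ", subject_id, ": mvc must be 10 positive values (N)")
  }
  names(mvc) <- channel_names()
  if (group == "control" && length(symptom_map) > 0) {
    stop("subject ", subject_id, ": controls must have an empty symptom_map")
  }
  parse_symptom_map(symptom_map)  # validates codes
  ord <- order(vapply(trials, `[[`, 1L, "block"),
               vapply(trials, `[[`, 1L, "trial"))
  structure(
    list(subject_id = as.character(subject_id), group = group,
         handedness = handedness, mvc = mvc,
         symptom_map = as.character(symptom_map),
         severity = severity, duration_years = duration_years, age = age,
         trials = trials[ord]),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s, %s-handed): %d trials, %d symptomatic finger(s)\n",
              x$subject_id, x$group, x$handedness, length(x$trials),
              length(x$symptom_map)))
  invisible(x)
}

#' Construct a cohort
#'
#' @param subjects list of [subject_record()] objects with unique ids.
#' @param provenance free-text origin (simulation seed/config, or file path).
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, provenance = "") {
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(subjects = subjects, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("<cohort> %d subjects (%d patient, %d control)\n",
              length(x$subjects), sum(grp == "patient"),
              sum(grp == "control")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

cohort_groups <- function(x) vapply(x$subjects, `[[`, "", "group")
cohort_ids <- function(x) vapply(x$subjects, `[[`, "", "subject_id")
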