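#' Fit a subject's finger-individuation profile
#'
#' The package's central fitting function. From a subject's raw force
#' trials it builds the baseline-corrected peak table and estimates all
#' four slope patterns: enslaving for each hand (20 pair-wise
#' origin-constrained robust log-slopes per hand) and mirroring for each
#' direction (25 per direction).
#'
#' @param subject a [subject_record()].
#' @return An object of class `individuation_fit` with elements `patterns`
#'   (named list `enslaving_L`, `enslaving_R`, `mirroring_RL`,
#'   `mirroring_LR`), `peaks`, and the subject's metadata.
#' @seealso [individuation_study()] for cohort-level fitting.
#' @export
individuation_fit <- function(subject) {
  stopifnot(inherits(subject, "subject_record"))
  peaks <- build_peak_table(subject)
  patterns <- list(
    enslaving_L = enslaving_pattern(peaks, "L"),
    enslaving_R = enslaving_pattern(peaks, "R"),
    mirroring_RL = mirroring_pattern(peaks, "R"),
    mirroring_LR = mirroring_pattern(peaks, "L"))
  structure(list(subject_id = subject$subject_id, group = subject$group,
                 symptom_map = subject$symptom_map, mvc = subject$mvc,
                 patterns = patterns, peaks = peaks),
            class = "individuation_fit")
}

# resolve a (kind, context) pair to the pattern slot name
pattern_slot <- function(kind, context) {
  kind <- match.arg(kind, c("enslaving", "mirroring"))
  if (kind == "enslaving") {
    context <- match.arg(context, c("R", "L"))
    paste0("enslaving_", context)
  } else {
    context <- match.arg(context, c("R->L", "L->R"))
    paste0("mirroring_", if (context == "R->L") "RL" else "LR")
  }
}

#' @export
print.individuation_fit <- function(x, ...) {
  cat(sprintf("<individuation_fit> %s (%s)\n", x$subject_id, x$group))
  s <- summary(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @describeIn individuation_fit mean log-slope and back-transformed
#'   strength (N/N) per kind/context.
#' @param object,x an `individuation_fit`.
#' @param ... unused.
#' @export
summary.individuation_fit <- function(object, ...) {
  rows <- lapply(object$patterns, function(p) {
    ms <- mean_pattern_strength(p)
    data.frame(kind = p$kind, context = p$context,
               mean_log_slope = ms$mean_log_slope,
               strength = ms$strength, n_cells = ms$n_cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn individuation_fit the 5 x 5 log-slope matrix for one
#'   kind/context (invalid cells `NA`); `backtransform = TRUE` returns raw
#'   slopes in N/N.
#' @param kind `"enslaving"` or `"mirroring"`.
#' @param context hand (`"R"`/`"L"`) or direction (`"R->L"`/`"L->R"`).
#' @param backtransform return slopes instead of log-slopes.
#' @export
coef.individuation_fit <- function(object, kind = "enslaving",
                                   context = "R", backtransform = FALSE,
                                   ...) {
  p <- object$patterns[[pattern_slot(kind, context)]]
  m <- if (backtransform) p$slopes else p$cells
  m[!p$valid] <- NA
  m
}

#' @describeIn individuation_fit heat-map image of the four patterns
#'   (base graphics).
#' @export
plot.individuation_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (p in x$patterns) {
    m <- p$cells
    m[!p$valid] <- NA
    graphics::image(1:5, 1:5, t(m[5:1, ]), axes = FALSE,
                    col = grDevices::hcl.colors(24, "Reds", rev = TRUE),
                    xlab = "uninstructed finger", ylab = "instructed finger",
                    main = sprintf("%s (%s)", p$kind, p$context), ...)
    graphics::axis(1, at = 1:5, labels = FINGERS)
    graphics::axis(2, at = 1:5, labels = rev(FINGERS))
    graphics::box()
  }
  invisible(x)
}

#' Fit every subject in a cohort
#'
#' Applies [individuation_fit()] to each subject and bundles the fits with
#' group labels for the cohort-level analyses (reliability, pattern
#' similarity, clinical contrasts).
#'
#' @param x a [cohort()].
#' @return An object of class `individuation_study`.
#' @export
individuation_study <- function(x) {
  stopifnot(inherits(x, "cohort"))
  fits <- lapply(x$subjects, individuation_fit)
  names(fits) <- cohort_ids(x)
  structure(list(fits = fits, group = cohort_groups(x), cohort = x),
            class = "individuation_study")
}

#' @export
print.individuation_study <- function(x, ...) {
  cat(sprintf("<individuation_study> %d subjects (%d patient, %d control)\n",
              length(x$fits), sum(x$group == "patient"),
              sum(x$group == "control")))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @describeIn individuation_study per-group mean strength (back-transformed
#'   geometric mean of per-subject strengths) for every kind/context.
#' @param object,x an `individuation_study`.
#' @param ... unused.
#' @export
summary.individuation_study <- function(object, ...) {
  per <- do.call(rbind, lapply(names(object$fits), function(id) {
    s <- summary(object$fits[[id]])
    s$subject_id <- id
    s$group <- object$fits[[id]]$group
    s
  }))
  agg <- stats::aggregate(mean_log_slope ~ kind + context + group,
                          data = per, FUN = mean)
  agg$strength <- exp(agg$mean_log_slope)
  agg$n_subjects <- stats::aggregate(mean_log_slope ~ kind + context + group,
                                     data = per, FUN = length)$mean_log_slope
  agg[order(agg$kind, agg$context, agg$group), ]
}

# per-subject mean log-slopes for one kind/context
study_metric <- function(study, kind, context) {
  slot <- pattern_slot(kind, context)
  vapply(study$fits, function(f)
    mean_pattern_strength(f$patterns[[slot]])$mean_log_slope, 0)
}
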