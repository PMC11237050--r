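#' Classify finger pairs by symptom status
#'
#' Labels each (instructed, uninstructed) cell of one hand's 5 x 5 pattern
#' by the clinical status of the two fingers: `sym-sym`, `sym-asy`,
#' `asy-sym` or `asy-asy` (instructed finger's status first). The diagonal
#' is `NA` (a finger cannot be enslaved to itself).
#'
#' @param symptom_map symptomatic-finger codes (see [parse_symptom_map()]).
#' @param hand the hand whose pattern is being classified.
#' @return A 5 x 5 character matrix with `NA` diagonal.
#' @export
classify_finger_pairs <- function(symptom_map, hand = c("R", "L")) {
  hand <- match.arg(hand)
  sym <- FINGERS %in% symptomatic_fingers(symptom_map, hand)
  lab <- ifelse(sym, "sym", "asy")
  m <- outer(lab, lab, function(a, b) paste0(a, "-", b))
  diag(m) <- NA_character_
  dimnames(m) <- list(instructed = FINGERS, uninstructed = FINGERS)
  m
}

new_ttest <- function(t, df, p, kind, means, label = "") {
  structure(list(t = t, df = df, p = p, kind = kind,
                 group_means = means, label = label),
            class = "findiv_ttest")
}

#' @export
print.findiv_ttest <- function(x, ...) {
  cat(sprintf("%s t(%d) = %.3f, p = %.3g  [%s]\n", x$kind, x$df, x$t, x$p,
              x$label))
  print(x$group_means)
  invisible(x)
}

#' Patients-vs-controls contrast of mean coupling strength
#'
#' Pooled-variance two-sample t-test on the per-subject mean log-slopes
#' for one kind/context; with `n1` patients and `n2` controls the degrees
#' of freedom are `n1 + n2 - 2`. The t statistic is signed patients minus
#' controls.
#'
#' @param study an [individuation_study()].
#' @param kind,context pattern selector.
#' @return A `findiv_ttest` with back-transformed group means (N/N).
#' @export
group_mean_comparison <- function(study, kind = "enslaving", context = "R") {
  m <- study_metric(study, kind, context)
  pat <- m[study$group == "patient"]
  con <- m[study$group == "control"]
  if (length(pat) < 2 || length(con) < 2) {
    stop("need at least 2 subjects per group")
  }
  tt <- pooled_t_test(pat, con)
  means <- c(patient = exp(mean(pat)), control = exp(mean(con)))
  new_ttest(tt$t, tt$df, tt$p, "two-sample pooled", means,
            label = sprintf("mean %s (%s), patients - controls",
                            kind, context))
}

#' Symptomatic-pair one-way ANOVA
#'
#' Within the patient group, averages each patient's enslaving log-slopes
#' within each pair category (`sym-sym` only exists for patients with at
#' least two symptomatic fingers on that hand) and runs a one-way ANOVA of
#' those per-patient category means across categories, with eta-squared
#' (SS_between / SS_total) as effect size and Tukey-Kramer post-hoc
#' comparisons for the unequal group sizes. A Levene-type check is not
#' gated on: Tukey is always reported.
#'
#' @param study an [individuation_study()] (only patients are used).
#' @param hand which hand's enslaving pattern to analyse.
#' @return A list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `eta_squared`, `tukey` (data frame of pairwise adjusted p), and
#'   the underlying `observations`.
#' @export
symptomatic_pair_anova <- function(study, hand = "R") {
  pat <- study$fits[study$group == "patient"]
  if (length(pat) < 2) stop("need at least 2 patients")
  slot <- pattern_slot("enslaving", hand)
  obs <- do.call(rbind, lapply(pat, function(f) {
    cat_m <- classify_finger_pairs(f$symptom_map, hand)
    p <- f$patterns[[slot]]
    ok <- p$valid & !is.na(cat_m)
    vals <- tapply(p$cells[ok], cat_m[ok], mean)
    data.frame(subject_id = f$subject_id, category = names(vals),
               value = as.numeric(vals), stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  present <- table(obs$category)
  if (any(present == 0)) {
    warning("empty pair categories dropped: ",
            paste(names(present)[present == 0], collapse = ", "))
  }
  obs$category <- factor(obs$category)
  sst <- sum((obs$value - mean(obs$value))^2)
  if (sst == 0) {
    res <- list(F = 0, df_between = nlevels(obs$category) - 1,
                df_within = nrow(obs) - nlevels(obs$category),
                p = 1, eta_squared = 0, tukey = NULL, observations = obs)
    class(res) <- "anova_result"
    return(res)
  }
  fit <- stats::aov(value ~ category, data = obs)
  an <- stats::anova(fit)
  ssb <- an["category", "Sum Sq"]
  tk <- stats::TukeyHSD(fit)$category
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  res <- list(F = an["category", "F value"],
              df_between = an["category", "Df"],
              df_within = an["Residuals", "Df"],
              p = an["category", "Pr(>F)"],
              eta_squared = ssb / sst, tukey = tukey, observations = obs)
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g, eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_squared))
  if (!is.null(x$tukey)) print(x$tukey, row.names = FALSE)
  invisible(x)
}

# per-patient paired means helper: mean mirroring log-slope over cells
# selected by a row (instructed) or column (passive) symptom mask.
paired_mirror_means <- function(study, slot, status_hand, by_row) {
  pat <- study$fits[study$group == "patient"]
  out <- lapply(pat, function(f) {
    sym <- FINGERS %in% symptomatic_fingers(f$symptom_map, status_hand)
    if (all(sym) || !any(sym)) {
      warning("patient ", f$subject_id,
              " has all-or-none symptomatic fingers; excluded")
      return(NULL)
    }
    p <- f$patterns[[slot]]
    mask <- if (by_row) matrix(sym, 5, 5) else matrix(sym, 5, 5, byrow = TRUE)
    c(sym = mean(p$cells[p$valid & mask]),
      asy = mean(p$cells[p$valid & !mask]))
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Does mirroring depend on the instructed finger's symptom status?
#'
#' For right-hand (symptomatic-hand) presses, compares each patient's mean
#' mirroring log-slope when the instructed finger is symptomatic versus
#' asymptomatic, with a paired t-test (df = n - 1). Patients whose right
#' hand is entirely symptomatic or entirely asymptomatic are excluded with
#' a warning.
#'
#' @param study an [individuation_study()].
#' @return A `findiv_ttest` (kind `"paired"`).
#' @export
instructed_symptom_mirroring_test <- function(study) {
  mm <- paired_mirror_means(study, "mirroring_RL", "R", by_row = TRUE)
  if (is.null(mm) || nrow(mm) < 2) stop("fewer than 2 usable patients")
  tt <- paired_t_test(mm[, "sym"], mm[, "asy"])
  new_ttest(tt$t, tt$df, tt$p, "paired",
            c(sym = exp(mean(mm[, "sym"])), asy = exp(mean(mm[, "asy"]))),
            label = "mirroring by instructed-finger status (right hand active)")
}

#' Behavioural test for mirror dystonia
#'
#' During left (asymptomatic) hand presses, compares the mirrored force
#' received by each patient's symptomatic versus asymptomatic right-hand
#' fingers (paired t-test over patients). A positive effect would indicate
#' that voluntary movement of the unaffected hand preferentially elicits
#' activity in the clinically affected fingers.
#'
#' @param study an [individuation_study()].
#' @return A `findiv_ttest` (kind `"paired"`).
#' @export
mirror_dystonia_test <- function(study) {
  mm <- paired_mirror_means(study, "mirroring_LR", "R", by_row = FALSE)
  if (is.null(mm) || nrow(mm) < 2) stop("fewer than 2 usable patients")
  tt <- paired_t_test(mm[, "sym"], mm[, "asy"])
  new_ttest(tt$t, tt$df, tt$p, "paired",
            c(sym = exp(mean(mm[, "sym"])), asy = exp(mean(mm[, "asy"]))),
            label = "mirroring onto symptomatic vs asymptomatic fingers (left hand active)")
}

#' Demographic and clinical summary
#'
#' Means and standard deviations (n - 1 denominator) of age, symptom
#' duration and severity per group, plus an unpaired pooled-variance
#' t-test on age when both groups have at least two subjects with known
#' age. Accepts a [cohort()] or a data frame with columns `group`, `age`,
#' `duration_years`, `severity`. Fields absent for a group are reported as
#' `NA`; a single observation has no SD.
#'
#' @param x a `cohort` or a demographics data frame.
#' @return A list with `table` (group x field means/SDs and n) and
#'   `age_test` (`findiv_ttest` or `NULL`).
#' @export
demographic_summary <- function(x) {
  if (inherits(x, "cohort")) {
    x <- data.frame(
      group = cohort_groups(x),
      age = vapply(x$subjects, `[[`, 0, "age"),
      duration_years = vapply(x$subjects, `[[`, 0, "duration_years"),
      severity = vapply(x$subjects, `[[`, 0, "severity"),
      stringsAsFactors = FALSE)
  }
  fields <- intersect(c("age", "duration_years", "severity"), names(x))
  rows <- lapply(split(x, x$group), function(d) {
    out <- data.frame(group = d$group[1], n = nrow(d))
    for (f in fields) {
      v <- d[[f]][!is.na(d[[f]])]
      out[[paste0(f, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(f, "_sd")]] <- if (length(v) >= 2) stats::sd(v) else NA_real_
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  age_test <- NULL
  if ("age" %in% fields && all(c("patient", "control") %in% x$group)) {
    a <- x$age[x$group == "patient"]
    b <- x$age[x$group == "control"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- pooled_t_test(a, b)
      age_test <- new_ttest(tt$t, tt$df, tt$p, "two-sample pooled",
                            c(patient = mean(a), control = mean(b)),
                            label = "age, patients - controls")
    }
  }
  list(table = tab, age_test = age_test)
}

#' Demographic table of the clinical musician cohort
#'
#' Published demographic and clinical details of the 11 musicians with
#' task-specific (musician's) dystonia whose study design this package's
#' simulator emulates: age, instrument, symptomatic digits (as `"R-D3"`
#' style codes; D1 = thumb ... D5 = little), symptom duration in years and
#' Tubiana-Chamagne severity (0-5). Used to anchor simulator defaults and
#' as worked-example input for the clinical statistics.
#'
#' @return A data frame, one row per patient.
#' @export
patient_demographics <- function() {
  path <- system.file("extdata", "patient_demographics.csv",
                      package = "findiv", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Symptom maps from a demographics table
#'
#' @param demo a data frame as returned by [patient_demographics()], with
#'   a `symptomatic_digits` column of semicolon-separated codes.
#' @return A named list of symptom-map character vectors.
#' @export
demographics_symptom_maps <- function(demo = patient_demographics()) {
  maps <- lapply(strsplit(demo$symptomatic_digits, ";"), trimws)
  names(maps) <- demo$patient
  maps
}
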