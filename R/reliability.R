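# Fisher-Z helpers: correlations are clamped just inside +/-1 before atanh
# so degenerate perfect correlations keep a finite Z.
fisher_z <- function(r, clamp = 1 - 1e-6) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Split-half reliability of a subject's pattern
#'
#' Splits the session into odd and even blocks (1-based block index),
#' estimates the pattern independently from each half and correlates the
#' cell values (Pearson) across the two halves over the cells valid in
#' both halves (pairwise-complete).
#'
#' @param subject a [subject_record()].
#' @param kind `"enslaving"` or `"mirroring"`.
#' @param context hand or direction, as in [coef.individuation_fit()].
#' @return The split-half correlation.
#' @export
split_half_reliability <- function(subject, kind = "enslaving",
                                   context = "R") {
  peaks <- build_peak_table(subject)
  blocks <- unique(peaks$block)
  if (!any(blocks %% 2 == 1) || !any(blocks %% 2 == 0)) {
    stop("subject ", subject$subject_id,
         ": need at least one odd and one even block")
  }
  halves <- lapply(list(odd = 1, even = 0), function(par) {
    half <- peaks[peaks$block %% 2 == par %% 2, , drop = FALSE]
    if (kind == "enslaving") enslaving_pattern(half, context)
    else mirroring_pattern(half, sub("->.*", "", context))
  })
  common <- halves$odd$valid & halves$even$valid
  if (sum(common) < 3) {
    stop("fewer than 3 cells estimable in both halves")
  }
  stats::cor(halves$odd$cells[common], halves$even$cells[common])
}

#' Group-level reliability with Fisher-Z pooling
#'
#' Averages per-subject split-half correlations on the Fisher-Z scale and
#' back-transforms; the 95% confidence interval is the Z-scale mean
#' +/- 1.96 standard errors (across subjects), back-transformed, so the
#' bounds always lie inside [-1, 1].
#'
#' @param subjects list of [subject_record()] objects (>= 2).
#' @param kind,context as in [split_half_reliability()].
#' @return A list of class `reliability_result`: per-subject `r`, group
#'   `mean_r`, `ci` bounds, `kind`, `context`.
#' @export
group_reliability <- function(subjects, kind = "enslaving", context = "R") {
  stopifnot(length(subjects) >= 2)
  r <- vapply(subjects, split_half_reliability, 0,
              kind = kind, context = context)
  names(r) <- vapply(subjects, `[[`, "", "subject_id")
  z <- fisher_z(r)
  zbar <- mean(z)
  se <- stats::sd(z) / sqrt(length(z))
  structure(list(r = r, mean_r = tanh(zbar),
                 ci = tanh(zbar + c(-1, 1) * 1.96 * se),
                 kind = kind, context = context),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "Split-half reliability (%s, %s): mean r = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
    x$kind, x$context, x$mean_r, x$ci[1], x$ci[2], length(x$r)))
  invisible(x)
}
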