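# Pooled-variance two-sample t-test by closed form. stats::t.test errors
# on zero-variance inputs, but the similarity and group contrasts must
# return t = 0, p = 1 for identical groups, so the textbook formula is
# used here and cross-checked against stats::t.test in the test suite.
pooled_t_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  ss <- function(v) if (length(v) < 2) 0 else (length(v) - 1) * stats::var(v)
  sp2 <- (ss(a) + ss(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

paired_t_test <- function(a, b) {
  d <- a - b
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- if (se == 0) 0 else mean(d) / se
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Cross-validated pattern-similarity contrast on raw cell vectors
#'
#' Core of the pattern-similarity analysis, operating on a subjects x cells
#' matrix of pattern values. Each patient's cells are correlated (Pearson)
#' with the cell-wise mean over *all* control patterns; each control is
#' correlated with the mean over the *other* controls (leave-one-out, so a
#' control's own data never biases its reference). Correlations are
#' clamped to +/-(1 - 1e-6), Fisher-Z transformed, and compared between
#' groups with a pooled-variance two-sample t-test.
#'
#' @param cells numeric matrix, one row per subject, one column per
#'   pattern cell (log-slopes).
#' @param group character vector, `"patient"`/`"control"` per row.
#' @return A list of class `similarity_result`: per-subject `r` and `z`,
#'   `group`, `t`, `df`, `p`, and `mean_patient_r` (back-transformed mean
#'   patient Fisher-Z).
#' @export
crossval_similarity <- function(cells, group) {
  stopifnot(nrow(cells) == length(group))
  is_con <- group == "control"
  if (sum(is_con) < 2) stop("need at least 2 controls")
  if (sum(!is_con) < 1) stop("need at least 1 patient")
  con_idx <- which(is_con)
  con_sum <- colSums(cells[con_idx, , drop = FALSE])
  n_con <- length(con_idx)

  r <- rep(NA_real_, length(group))
  for (i in seq_along(group)) {
    own <- cells[i, ]
    ref <- if (is_con[i]) (con_sum - own) / (n_con - 1) else con_sum / n_con
    if (stats::sd(own) == 0 || stats::sd(ref) == 0) {
      warning("zero-variance pattern for subject ", i,
              "; excluded from the similarity contrast")
      next
    }
    r[i] <- stats::cor(own, ref)
  }
  keep <- !is.na(r)
  z <- fisher_z(r)
  tt <- pooled_t_test(z[keep & !is_con], z[keep & is_con])
  structure(list(r = r, z = z, group = group, t = tt$t, df = tt$df,
                 p = tt$p,
                 mean_patient_r = tanh(mean(z[keep & !is_con]))),
            class = "similarity_result")
}

#' Between-group pattern similarity for a fitted study
#'
#' Extracts every subject's valid pattern cells for one kind/context
#' (cells must be valid for all subjects to enter the comparison) and runs
#' [crossval_similarity()] patients vs controls.
#'
#' @param study an [individuation_study()].
#' @param kind,context pattern selector, as in [coef.individuation_fit()].
#' @return A `similarity_result` (see [crossval_similarity()]); per-subject
#'   values are named by subject id.
#' @export
crossval_pattern_similarity <- function(study, kind = "enslaving",
                                        context = "R") {
  slot <- pattern_slot(kind, context)
  pats <- lapply(study$fits, function(f) f$patterns[[slot]])
  valid_all <- Reduce(`&`, lapply(pats, `[[`, "valid"))
  if (sum(valid_all) < 3) stop("fewer than 3 cells valid across all subjects")
  cells <- do.call(rbind, lapply(pats, function(p) p$cells[valid_all]))
  res <- crossval_similarity(cells, study$group)
  names(res$r) <- names(res$z) <- names(study$fits)
  res
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "Pattern similarity: mean patient r = %.3f; patients vs controls t(%d) = %.3f, p = %.3g\n",
    x$mean_patient_r, x$df, x$t, x$p))
  invisible(x)
}
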