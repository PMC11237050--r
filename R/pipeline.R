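# Orchestration: simulate -> analyze -> report as reproducible runs.
# Results go to files; progress messages go to stderr via message().

config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(cohort_config, cfg)
}

config_hash <- function(config) {
  h <- fnv1a32(paste(names(config), unlist(config), collapse = ";"))
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Simulate a cohort to disk
#'
#' Runs [simulate_cohort()] and writes the cohort files plus
#' `ground_truth.json` (per-subject coupling matrices) under `out_dir`.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config a [cohort_config()] or the path to a YAML file with its
#'   fields (unknown keys are rejected).
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @return The manifest path, invisibly.
#' @export
run_simulation <- function(config = cohort_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- seed
  message("simulating ", config$n_patients, " patients + ",
          config$n_controls, " controls (seed ", config$seed, ")")
  sim <- simulate_cohort(config)
  manifest <- write_cohort(sim$cohort, out_dir)
  gt <- lapply(sim$ground_truth, function(m) {
    lapply(m[c("E_L", "E_R", "M_RL", "M_LR")], function(x)
      as.data.frame(unclass(x)))
  })
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         config = unclass(config), models = gt),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(manifest)
}

#' Analyze a cohort end to end
#'
#' Fits every subject ([individuation_study()]) and writes the analysis
#' tables under `out_dir`: `patterns.csv` (every pair-wise log-slope),
#' `reliability.csv`, `similarity.csv`, `stats_report.json` (clinical
#' tests) and `summary.json` (group-level roll-up with provenance).
#' Analysis sections can be toggled off.
#'
#' @param input a [cohort()], an [individuation_study()], or a manifest
#'   path readable by [read_cohort()].
#' @param out_dir output directory.
#' @param analyses subset of
#'   `c("enslaving", "mirroring", "reliability", "similarity", "clinical")`.
#' @param seed recorded in the outputs for provenance.
#' @return The [individuation_study()], invisibly.
#' @export
run_analysis <- function(input, out_dir,
                         analyses = c("enslaving", "mirroring",
                                      "reliability", "similarity",
                                      "clinical"),
                         seed = NA) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(input)) input <- read_cohort(input)
  study <- if (inherits(input, "individuation_study")) input
           else individuation_study(input)
  coh <- study$cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  kinds <- intersect(c("enslaving", "mirroring"), analyses)
  contexts <- list(enslaving = c("L", "R"), mirroring = c("R->L", "L->R"))

  pat_rows <- list()
  for (id in names(study$fits)) {
    f <- study$fits[[id]]
    for (p in f$patterns) {
      if (!p$kind %in% kinds) next
      idx <- which(p$valid)
      pat_rows[[length(pat_rows) + 1L]] <- data.frame(
        subject_id = id, kind = p$kind, context = p$context,
        instructed = FINGERS[row(p$valid)[idx]],
        uninstructed = FINGERS[col(p$valid)[idx]],
        log_slope = p$cells[idx], n_points = p$n_points[idx],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, pat_rows),
                   file.path(out_dir, "patterns.csv"), row.names = FALSE)

  summary_obj <- list(seed = seed, provenance = coh$provenance,
                      group_means = summary(study))

  if ("reliability" %in% analyses && length(coh$subjects) >= 2) {
    rel_rows <- list()
    for (k in kinds) {
      for (ctx in contexts[[k]]) {
        for (g in unique(study$group)) {
          subs <- coh$subjects[study$group == g]
          if (length(subs) < 2) next
          rr <- group_reliability(subs, k, ctx)
          rel_rows[[length(rel_rows) + 1L]] <- data.frame(
            kind = k, context = ctx, group = g, mean_r = rr$mean_r,
            ci_lo = rr$ci[1], ci_hi = rr$ci[2], n = length(rr$r),
            stringsAsFactors = FALSE)
        }
      }
    }
    rel <- do.call(rbind, rel_rows)
    utils::write.csv(rel, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
    summary_obj$reliability <- rel
  }

  both_groups <- all(c("patient", "control") %in% study$group) &&
    sum(study$group == "control") >= 2 && sum(study$group == "patient") >= 1
  if ("similarity" %in% analyses && both_groups) {
    sim_rows <- list()
    sim_tests <- list()
    for (k in kinds) {
      for (ctx in contexts[[k]]) {
        sr <- crossval_pattern_similarity(study, k, ctx)
        sim_rows[[length(sim_rows) + 1L]] <- data.frame(
          kind = k, context = ctx, subject_id = names(sr$r),
          group = sr$group, r = sr$r, stringsAsFactors = FALSE)
        sim_tests[[paste(k, ctx)]] <- list(
          t = sr$t, df = sr$df, p = sr$p,
          mean_patient_r = sr$mean_patient_r)
      }
    }
    utils::write.csv(do.call(rbind, sim_rows),
                     file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
    summary_obj$similarity_tests <- sim_tests
  }

  if ("clinical" %in% analyses) {
    stats_report <- list()
    if (both_groups && sum(study$group == "patient") >= 2) {
      for (k in kinds) {
        for (ctx in contexts[[k]]) {
          gm <- group_mean_comparison(study, k, ctx)
          stats_report[[paste0("group_", k, "_", gsub("->", "", ctx))]] <-
            list(t = gm$t, df = gm$df, p = gm$p,
                 means = as.list(gm$group_means))
        }
      }
    }
    n_pat <- sum(study$group == "patient")
    if (n_pat >= 2) {
      an <- try(symptomatic_pair_anova(study, "R"), silent = TRUE)
      if (!inherits(an, "try-error")) {
        stats_report$symptomatic_pair_anova <- list(
          F = an$F, df_between = an$df_between, df_within = an$df_within,
          p = an$p, eta_squared = an$eta_squared)
      }
      for (nm in c("instructed_symptom_mirroring_test",
                   "mirror_dystonia_test")) {
        tt <- try(suppressWarnings(do.call(nm, list(study))), silent = TRUE)
        if (!inherits(tt, "try-error")) {
          stats_report[[nm]] <- list(t = tt$t, df = tt$df, p = tt$p)
        }
      }
    }
    ds <- demographic_summary(coh)
    stats_report$demographics <- ds$table
    if (!is.null(ds$age_test)) {
      stats_report$age_test <- list(t = ds$age_test$t, df = ds$age_test$df,
                                    p = ds$age_test$p)
    }
    jsonlite::write_json(stats_report,
                         file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    summary_obj$clinical <- stats_report
  }

  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(study)
}

#' Render a plain-text analysis report
#'
#' Reads the tables produced by [run_analysis()] from `results_dir` and
#' writes `report.md`, a human-readable markdown summary: group mean
#' strengths, reliability with confidence intervals, similarity tests,
#' clinical contrasts, and 5 x 5 text renderings of the group-average
#' patterns. Regenerating from unchanged inputs gives identical bytes.
#'
#' @param results_dir directory holding `run_analysis()` outputs.
#' @return The report path, invisibly.
#' @export
run_report <- function(results_dir) {
  need <- c("patterns.csv", "summary.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing)) {
    stop("missing analysis output(s) in ", results_dir, ": ",
         paste(missing, collapse = ", "))
  }
  pats <- utils::read.csv(file.path(results_dir, "patterns.csv"),
                          stringsAsFactors = FALSE)
  summ <- jsonlite::read_json(file.path(results_dir, "summary.json"))

  lines <- c("# Finger individuation report", "",
             sprintf("Provenance: %s (seed %s)", summ$provenance,
                     if (is.null(summ$seed)) "NA" else format(summ$seed)),
             "")
  lines <- c(lines, "## Group mean coupling strength (N/N)", "",
             "| kind | context | group | strength |",
             "|---|---|---|---|")
  for (g in summ$group_means) {
    lines <- c(lines, sprintf("| %s | %s | %s | %.4f |", g$kind, g$context,
                              g$group, g$strength))
  }
  if (!is.null(summ$reliability)) {
    lines <- c(lines, "", "## Split-half reliability", "",
               "| kind | context | group | mean r | 95% CI |",
               "|---|---|---|---|---|")
    for (r in summ$reliability) {
      lines <- c(lines, sprintf("| %s | %s | %s | %.3f | [%.3f, %.3f] |",
                                r$kind, r$context, r$group, r$mean_r,
                                r$ci_lo, r$ci_hi))
    }
  }
  if (!is.null(summ$similarity_tests)) {
    lines <- c(lines, "", "## Cross-validated pattern similarity", "",
               "| pattern | mean patient r | t | df | p |",
               "|---|---|---|---|---|")
    for (nm in names(summ$similarity_tests)) {
      s <- summ$similarity_tests[[nm]]
      lines <- c(lines, sprintf("| %s | %.3f | %.3f | %d | %.3g |", nm,
                                s$mean_patient_r, s$t, s$df, s$p))
    }
  }
  if (!is.null(summ$clinical)) {
    lines <- c(lines, "", "## Clinical contrasts", "")
    for (nm in setdiff(names(summ$clinical), c("demographics"))) {
      s <- summ$clinical[[nm]]
      if (!is.null(s$F)) {
        lines <- c(lines, sprintf("- %s: F(%d, %d) = %.3f, p = %.3g, eta^2 = %.3f",
                                  nm, s$df_between, s$df_within, s$F, s$p,
                                  s$eta_squared))
      } else if (!is.null(s$t)) {
        lines <- c(lines, sprintf("- %s: t(%d) = %.3f, p = %.3g", nm, s$df,
                                  s$t, s$p))
      }
    }
  }
  # group-average 5x5 pattern renderings
  for (k in unique(pats$kind)) {
    for (ctx in unique(pats$context[pats$kind == k])) {
      d <- pats[pats$kind == k & pats$context == ctx, ]
      m <- tapply(d$log_slope, list(d$instructed, d$uninstructed), mean)
      lines <- c(lines, "", sprintf("## Mean %s pattern (%s), log-slope", k, ctx),
                 "", paste0("| | ", paste(colnames(m), collapse = " | "), " |"),
                 paste0("|", paste(rep("---", ncol(m) + 1), collapse = "|"), "|"))
      for (i in rownames(m)) {
        vals <- ifelse(is.na(m[i, ]), "--", sprintf("%.3f", m[i, ]))
        lines <- c(lines, paste0("| ", i, " | ",
                                 paste(vals, collapse = " | "), " |"))
      }
    }
  }
  path <- file.path(results_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
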