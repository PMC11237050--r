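#' Cohort simulation configuration
#'
#' Defines the study conditions a simulated cohort emulates: 11 patients
#' vs 7 controls, 10 blocks of 30 trials (3 target levels x 10 fingers),
#' group geometric-mean enslaving 0.046 vs 0.028 N/N and mirroring 0.009
#' vs 0.006 N/N, with neighbour-biased coupling structure, between-subject
#' variability and signal-dependent motor noise.
#'
#' @param n_patients,n_controls group sizes.
#' @param control_geomean_enslaving control-group geometric-mean enslaving
#'   gain (N enslaved per N instructed).
#' @param patient_gain multiplicative patient/control ratio of enslaving.
#' @param control_geomean_mirroring control-group geometric-mean mirroring
#'   gain (N/N).
#' @param patient_mirror_gain multiplicative patient/control mirroring ratio.
#' @param symsym_extra_gain extra multiplier on enslaving cells where both
#'   fingers of the pair are clinically symptomatic on that hand.
#' @param distance_decay per-finger-of-separation log-linear falloff of the
#'   coupling structure (0 = flat pattern); neighbouring fingers couple more.
#' @param between_subject_cv coefficient of variation of a subject's overall
#'   coupling level around the group geometric mean; within-pattern cell
#'   jitter uses half this log-sd so `between_subject_cv = 0` yields exactly
#'   uniform patterns.
#' @param sd_signal signal-dependent noise coefficient: at every instant the
#'   sd of a channel's force noise is `sd_signal` times its coupled force.
#' @param sd_const constant (signal-independent) noise floor, N.
#' @param match_cv coefficient of variation of the target-matching error of
#'   the achieved instructed peak.
#' @param baseline_sd sd of per-trial, per-finger resting baseline offsets, N.
#' @param blocks number of blocks (>= 2 so split-half has both parities).
#' @param seed master seed; every subject derives a named stream from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 11, n_controls = 7,
                          control_geomean_enslaving = 0.028,
                          patient_gain = 0.046 / 0.028,
                          control_geomean_mirroring = 0.006,
                          patient_mirror_gain = 0.009 / 0.006,
                          symsym_extra_gain = 1.25,
                          distance_decay = 0.5,
                          between_subject_cv = 0.35,
                          sd_signal = 0.30, sd_const = 0.005,
                          match_cv = 0.08, baseline_sd = 0.05,
                          blocks = 10, seed = 1) {
  stopifnot(n_patients >= 0, n_controls >= 0, blocks >= 2,
            patient_gain > 0, patient_mirror_gain > 0, symsym_extra_gain > 0,
            control_geomean_enslaving > 0, control_geomean_mirroring > 0,
            between_subject_cv >= 0, sd_signal >= 0, sd_const >= 0,
            match_cv >= 0, baseline_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Turn off every noise source of a configuration
#'
#' Convenience for identifiability checks: with all noise terms zero the
#' pipeline must recover the ground-truth coupling matrices exactly.
#'
#' @param config a [cohort_config()].
#' @return The configuration with all stochastic terms set to zero.
#' @export
noise_free <- function(config) {
  config$sd_signal <- 0
  config$sd_const <- 0
  config$match_cv <- 0
  config$baseline_sd <- 0
  config$between_subject_cv <- 0
  config
}

# Structural (distance-decay) multiplier matrix, geometric mean 1 over the
# cells that enter the pattern. For enslaving the relevant separation is
# |i - j| - 1 (adjacent fingers = no penalty, diagonal unused); for
# mirroring it is |i - j| (homologous finger pairs mirror most).
decay_structure <- function(decay, kind) {
  d <- abs(outer(1:5, 1:5, "-"))
  if (kind == "enslaving") {
    lg <- -decay * (d - 1)
    diag(lg) <- NA
  } else {
    lg <- -decay * d
  }
  lg <- lg - mean(lg, na.rm = TRUE)
  m <- exp(lg)
  if (kind == "enslaving") diag(m) <- NA
  dimnames(m) <- list(FINGERS, FINGERS)
  m
}

#' Draw a subject's ground-truth coupling model
#'
#' Builds the enslaving matrices (`E_L`, `E_R`; rows = instructed finger,
#' columns = uninstructed finger, diagonal fixed at 1) and mirroring
#' matrices (`M_RL`: right hand active, left passive; `M_LR`: the reverse)
#' for one simulated subject. Off-diagonal cells are log-normal around the
#' group geometric mean, shaped by the distance-decay structure, with a
#' subject-level log offset (sd from `between_subject_cv`) and per-cell
#' jitter at half that log-sd. Cells where both fingers are symptomatic on
#' the same hand are multiplied by `symsym_extra_gain`. All off-diagonal
#' couplings are clipped to [0, 0.5].
#'
#' @param config a [cohort_config()].
#' @param group `"patient"` or `"control"`.
#' @param symptom_map symptomatic-finger codes (empty for controls).
#' @param seed integer seed for this subject's stream.
#' @return An object of class `coupling_model` with elements `E_L`, `E_R`,
#'   `M_RL`, `M_LR`, `mvc`, and the noise parameters.
#' @export
make_coupling_model <- function(config, group = c("control", "patient"),
                                symptom_map = character(), seed = 1) {
  group <- match.arg(group)
  if (group == "control" && length(symptom_map) > 0) {
    stop("controls cannot carry a symptom_map")
  }
  with_seed(seed, {
    s_subj <- sqrt(log(1 + config$between_subject_cv^2))
    s_cell <- s_subj / 2
    gm_e <- config$control_geomean_enslaving *
      if (group == "patient") config$patient_gain else 1
    gm_m <- config$control_geomean_mirroring *
      if (group == "patient") config$patient_mirror_gain else 1

    draw <- function(gm, kind, subj_off) {
      base <- decay_structure(config$distance_decay, kind)
      jit <- matrix(stats::rnorm(25, 0, s_cell), 5, 5)
      m <- gm * base * exp(subj_off + jit)
      m[] <- pmin(pmax(m, 0), 0.5)
      if (kind == "enslaving") diag(m) <- 1
      dimnames(m) <- list(FINGERS, FINGERS)
      m
    }
    off_e <- stats::rnorm(1, 0, s_subj)
    off_m <- stats::rnorm(1, 0, s_subj)
    E_L <- draw(gm_e, "enslaving", off_e)
    E_R <- draw(gm_e, "enslaving", off_e)
    M_RL <- draw(gm_m, "mirroring", off_m)
    M_LR <- draw(gm_m, "mirroring", off_m)

    for (h in HANDS) {
      sym <- symptomatic_fingers(symptom_map, h)
      if (length(sym) >= 2) {
        idx <- match(sym, FINGERS)
        boost <- matrix(FALSE, 5, 5)
        boost[idx, idx] <- TRUE
        diag(boost) <- FALSE
        m <- if (h == "L") E_L else E_R
        m[boost] <- pmin(m[boost] * config$symsym_extra_gain, 0.5)
        if (h == "L") E_L <- m else E_R <- m
      }
    }

    # MVC ~ Normal(20, 2) N truncated to [14, 24]: keeps the 75% target
    # below 18 N, inside the 0-25 N transducer range even with noise.
    mvc <- stats::rnorm(10, 20, 2)
    mvc <- pmin(pmax(mvc, 14), 24)
    names(mvc) <- channel_names()

    structure(list(E_L = E_L, E_R = E_R, M_RL = M_RL, M_LR = M_LR,
                   mvc = mvc, sd_signal = config$sd_signal,
                   sd_const = config$sd_const, match_cv = config$match_cv,
                   baseline_sd = config$baseline_sd),
              class = "coupling_model")
  })
}

# White noise low-pass filtered with a 0.25 s moving average, rescaled to a
# marginal sd of `sd`. Slow noise mimics force drifts and keeps the peak
# extractor's max-over-window from systematically inflating small signals.
smooth_noise <- function(n, sd, fs = 200) {
  if (sd == 0) return(numeric(n))
  win <- max(1L, round(0.25 * fs))
  w <- stats::rnorm(n + win - 1)
  sm <- as.numeric(stats::filter(w, rep(1 / win, win), sides = 1))
  sm <- sm[win:(n + win - 1)]
  sm * sd * sqrt(win)
}

#' Simulate one force trial
#'
#' Generates the instructed finger's drive trace -- preparation at rest
#' (uniform 2-3 s), a 0.3 s half-cosine ramp to the achieved peak
#' `target_level * MVC * (1 + eps)` with `eps ~ N(0, match_cv)`, a hold
#' (uniform 2-3 s) and a 0.5 s half-cosine release -- and propagates it to
#' every channel through the coupling matrices. Each channel receives a
#' per-trial gain perturbation of sd `sd_signal` (so the instantaneous
#' noise sd is proportional to its coupled force), a slow constant noise
#' floor of sd `sd_const`, and a resting baseline offset
#' `~ N(0, baseline_sd)`. Samples are clipped to the transducer range
#' [-1, 25] N.
#'
#' @param model a [make_coupling_model()] result.
#' @param instructed_hand,instructed_finger the instructed digit.
#' @param target_level fraction of MVC in {0.25, 0.5, 0.75}.
#' @param subject_id,block,trial design metadata for the returned trial.
#' @return A [force_trial()].
#' @export
simulate_trial <- function(model, instructed_hand, instructed_finger,
                           target_level, subject_id = "sim",
                           block = 1L, trial = 1L) {
  stopifnot(target_level %in% c(0.25, 0.5, 0.75))
  fs <- 200
  n_prep <- round(stats::runif(1, 2, 3) * fs)
  n_ramp <- round(0.3 * fs)
  n_hold <- round(stats::runif(1, 2, 3) * fs)
  n_rel <- round(0.5 * fs)
  n <- n_prep + n_ramp + n_hold + n_rel

  chan <- channel_index(instructed_hand, instructed_finger)
  peak <- target_level * model$mvc[chan] *
    (1 + stats::rnorm(1, 0, model$match_cv))

  drive <- c(rep(0, n_prep),
             peak * (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2,
             rep(peak, n_hold),
             peak * (1 + cos(pi * seq_len(n_rel) / n_rel)) / 2)

  # coupling gain of every channel w.r.t. the instructed finger's drive
  fi <- match(instructed_finger, FINGERS)
  if (instructed_hand == "L") {
    same <- model$E_L[fi, ]
    mirr <- model$M_LR[fi, ]
    gains <- c(same, mirr)
  } else {
    same <- model$E_R[fi, ]
    mirr <- model$M_RL[fi, ]
    gains <- c(mirr, same)
  }

  eta <- stats::rnorm(10, 0, 1)
  baseline <- stats::rnorm(10, 0, model$baseline_sd)
  # the coupling source is the instructed finger's *actual* force trace,
  # including its own trial-to-trial gain perturbation
  actual <- drive * (1 + model$sd_signal * eta[chan])
  forces <- matrix(0, n, 10)
  for (g in 1:10) {
    coupled <- if (g == chan) actual
               else gains[g] * actual * (1 + model$sd_signal * eta[g])
    forces[, g] <- coupled + smooth_noise(n, model$sd_const, fs) + baseline[g]
  }
  forces[] <- pmin(pmax(forces, -1), 25)

  force_trial(subject_id = subject_id, block = block, trial = trial,
              instructed_hand = instructed_hand,
              instructed_finger = instructed_finger,
              target_level = target_level, forces = forces,
              go_cue = n_prep + 1L, trial_end = n_prep + n_ramp + n_hold)
}

#' Simulate a full subject session
#'
#' Runs `config$blocks` blocks of 30 trials; within each block every
#' (hand-finger, target-level) combination appears exactly once in
#' pseudo-random order.
#'
#' @param model the subject's [make_coupling_model()].
#' @param config a [cohort_config()].
#' @param subject_id id for the record.
#' @param group `"patient"` or `"control"`.
#' @param symptom_map symptomatic-finger codes.
#' @param seed seed for this subject's trial stream.
#' @param severity,duration_years,age optional clinical covariates.
#' @return A [subject_record()].
#' @export
simulate_subject <- function(model, config, subject_id, group,
                             symptom_map = character(), seed = 1,
                             severity = NA_real_,
                             duration_years = NA_real_, age = NA_real_) {
  design <- expand.grid(finger = FINGERS, hand = HANDS,
                        level = c(0.25, 0.5, 0.75),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    trials <- vector("list", config$blocks * nrow(design))
    k <- 0L
    for (b in seq_len(config$blocks)) {
      ord <- design[sample.int(nrow(design)), , drop = FALSE]
      for (t in seq_len(nrow(ord))) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(
          model, ord$hand[t], ord$finger[t], ord$level[t],
          subject_id = subject_id, block = b, trial = t)
      }
    }
    subject_record(subject_id = subject_id, group = group, handedness = "R",
                   mvc = model$mvc, symptom_map = symptom_map,
                   trials = trials, severity = severity,
                   duration_years = duration_years, age = age)
  })
}

# Sample a patient's symptomatic fingers: 1-3 contiguous right-hand digits
# (weights from the published cohort: 5/11 one digit, 5/11 two, 1/11 three)
# and, with probability 2/11, additionally the left thumb.
sample_symptom_map <- function() {
  n_digits <- sample(1:3, 1, prob = c(5, 5, 1))
  start <- sample.int(5 - n_digits + 1, 1)
  codes <- paste0("R-", FINGERS[start:(start + n_digits - 1)])
  if (stats::runif(1) < 2 / 11) codes <- c(codes, "L-D1")
  codes
}

#' Simulate a cohort with known ground truth
#'
#' Generates `n_patients` patients (symptom maps always include at least
#' one right-hand digit; about 2/11 also involve the left thumb, matching
#' the clinical cohort) and `n_controls` controls. Each subject's coupling
#' model and trials are drawn from a named stream derived from the master
#' seed, so the data for a given subject id does not depend on cohort
#' composition or order.
#'
#' @param config a [cohort_config()].
#' @param symptom_maps optional list of symptom-map character vectors, one
#'   per patient (e.g. from [demographics_symptom_maps()]), used instead of
#'   sampling; must have at least `n_patients` entries.
#' @return A list with elements `cohort` (a [cohort()]) and `ground_truth`
#'   (named list of per-subject [make_coupling_model()] objects).
#' @export
simulate_cohort <- function(config, symptom_maps = NULL) {
  if (!is.null(symptom_maps) && length(symptom_maps) < config$n_patients) {
    stop("need at least n_patients symptom maps")
  }
  ids <- c(sprintf("P%02d", seq_len(config$n_patients)),
           sprintf("C%02d", seq_len(config$n_controls)))
  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  subjects <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  names(truth) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    sm <- if (groups[i] != "patient") character()
    else if (!is.null(symptom_maps)) symptom_maps[[i]]
    else with_seed(derive_seed(config$seed, paste0(id, "/symptoms")),
                   sample_symptom_map())
    covs <- with_seed(derive_seed(config$seed, paste0(id, "/covariates")), {
      if (groups[i] == "patient") {
        list(age = round(stats::rnorm(1, 49.9, 7.85)),
             duration = max(1, round(stats::rnorm(1, 7.8, 7.2))),
             severity = sample(2:4, 1, prob = c(6, 4, 1)))
      } else {
        list(age = round(stats::rnorm(1, 41.0, 14.5)),
             duration = NA_real_, severity = NA_real_)
      }
    })
    model <- make_coupling_model(config, groups[i], sm,
                                 seed = derive_seed(config$seed,
                                                    paste0(id, "/model")))
    truth[[i]] <- model
    subjects[[i]] <- simulate_subject(
      model, config, id, groups[i], sm,
      seed = derive_seed(config$seed, paste0(id, "/trials")),
      severity = covs$severity, duration_years = covs$duration,
      age = covs$age)
  }
  list(cohort = cohort(subjects,
                       provenance = sprintf("simulated (seed %s)",
                                            format(config$seed))),
       ground_truth = truth)
}
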