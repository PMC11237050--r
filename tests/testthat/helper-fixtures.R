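# Fixtures built in code: small simulated subjects and hand-constructed
# study objects whose pattern cells are known exactly.

# a quick configuration for unit tests: fewer blocks, one subject per group
quick_config <- function(..., blocks = 2, seed = 101) {
  cohort_config(n_patients = 1, n_controls = 1, blocks = blocks,
                seed = seed, ...)
}

# a deterministic coupling model with every off-diagonal coupling equal
uniform_model <- function(e = 0.05, m = 0.006, mvc = 20, config = NULL) {
  if (is.null(config)) {
    config <- noise_free(cohort_config(distance_decay = 0))
  }
  mod <- make_coupling_model(config, "control", seed = 1)
  for (nm in c("E_L", "E_R")) {
    mod[[nm]][] <- e
    diag(mod[[nm]]) <- 1
  }
  mod$M_RL[] <- m
  mod$M_LR[] <- m
  mod$mvc[] <- mvc
  mod
}

# build a slope_pattern with prescribed log-slope cells
fake_pattern <- function(cells, kind = "enslaving", context = "R") {
  valid <- matrix(TRUE, 5, 5)
  if (kind == "enslaving") diag(valid) <- FALSE
  cells[!valid] <- NA
  findiv:::new_slope_pattern(kind, context, cells, exp(cells), valid,
                             matrix(30L, 5, 5))
}

# an individuation_study whose per-subject patterns are given directly:
# `cells` is a named list (subject id -> list of 5x5 log-slope matrices for
# slots enslaving_L/enslaving_R/mirroring_RL/mirroring_LR; missing slots are
# filled with the enslaving_R matrix).
fake_study <- function(cells, groups, symptom_maps = NULL) {
  ids <- names(cells)
  fits <- lapply(seq_along(ids), function(i) {
    spec <- cells[[i]]
    if (is.matrix(spec)) spec <- list(enslaving_R = spec)
    base <- spec$enslaving_R
    patterns <- list(
      enslaving_L = fake_pattern(spec$enslaving_L %||% base, "enslaving", "L"),
      enslaving_R = fake_pattern(spec$enslaving_R %||% base, "enslaving", "R"),
      mirroring_RL = fake_pattern(spec$mirroring_RL %||% base,
                                  "mirroring", "R->L"),
      mirroring_LR = fake_pattern(spec$mirroring_LR %||% base,
                                  "mirroring", "L->R"))
    structure(list(subject_id = ids[i], group = groups[i],
                   symptom_map = symptom_maps[[ids[i]]] %||% character(),
                   mvc = rep(20, 10), patterns = patterns, peaks = NULL),
              class = "individuation_fit")
  })
  names(fits) <- ids
  structure(list(fits = fits, group = groups, cohort = NULL),
            class = "individuation_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one simulated subject, optionally noise-free
sim_subject <- function(seed = 101, blocks = 2, noise = TRUE, group = "control",
                        symptom_map = character(), config = NULL) {
  if (is.null(config)) {
    config <- cohort_config(blocks = blocks, seed = seed)
    if (!noise) config <- noise_free(config)
  }
  model <- make_coupling_model(config, group, symptom_map,
                               seed = derive(seed, "model"))
  subject <- simulate_subject(model, config, paste0("S", seed), group,
                              symptom_map, seed = derive(seed, "trials"))
  list(subject = subject, model = model, config = config)
}

derive <- function(seed, key) findiv:::derive_seed(seed, key)
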