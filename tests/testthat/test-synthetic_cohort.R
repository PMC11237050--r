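test_that("coupling model honours group means, scaling and symptom boosts", {
  cfg <- noise_free(cohort_config(distance_decay = 0))
  con <- make_coupling_model(cfg, "control", seed = 5)
  off <- row(con$E_R) != col(con$E_R)
  expect_equal(unname(con$E_R[off]), rep(0.028, 20))
  expect_equal(unname(con$M_RL), matrix(0.006, 5, 5), ignore_attr = TRUE)
  expect_equal(unname(diag(con$E_R)), rep(1, 5))

  pat <- make_coupling_model(cfg, "patient", c("R-D3"), seed = 5)
  expect_equal(unname(pat$E_R[off]), rep(0.028 * cfg$patient_gain, 20))

  cfg2 <- cfg
  cfg2$symsym_extra_gain <- 2
  boosted <- make_coupling_model(cfg2, "patient", c("R-D3", "R-D4"), seed = 5)
  plain <- make_coupling_model(cfg, "patient", c("R-D3", "R-D4"), seed = 5)
  expect_equal(boosted$E_R["D3", "D4"], 2 * 0.028 * cfg$patient_gain)
  expect_equal(boosted$E_R["D4", "D3"] / plain$E_R["D4", "D3"],
               2 / cfg$symsym_extra_gain)
  expect_equal(boosted$E_R["D2", "D3"], plain$E_R["D2", "D3"])  # asy-sym cell

  expect_error(make_coupling_model(cfg, "control", c("R-D3"), seed = 1),
               "symptom_map")
})

test_that("noise-free trials hit targets and couplings exactly", {
  mod <- uniform_model(e = 0.05, m = 0.006, mvc = 20)
  set.seed(1)
  tr <- simulate_trial(mod, "R", "D2", 0.5)
  pk <- extract_peaks(tr, mvc = mod$mvc)
  expect_equal(pk$peak_R_D2, 10.0)
  expect_true(pk$in_zone)
  expect_equal(pk$peak_R_D4, 0.5)      # 0.05 x 10 N enslaved
  expect_equal(pk$peak_L_D2, 0.06)     # 0.006 x 10 N mirrored
})

test_that("achieved peaks are unbiased around the target under noise", {
  cfg <- cohort_config()
  mod <- uniform_model(config = cfg)
  mod$sd_signal <- cfg$sd_signal; mod$sd_const <- cfg$sd_const
  mod$match_cv <- cfg$match_cv; mod$baseline_sd <- cfg$baseline_sd
  set.seed(99)
  peaks <- replicate(200, {
    tr <- simulate_trial(mod, "R", "D3", 0.5)
    extract_peaks(tr)$peak_R_D3
  })
  target <- 0.5 * mod$mvc[["R_D3"]]
  se <- sd(peaks) / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - target), 2 * se)
})

test_that("sessions are balanced and reproducible", {
  cfg <- cohort_config(blocks = 3, seed = 4)
  mod <- make_coupling_model(cfg, "control", seed = 4)
  s1 <- simulate_subject(mod, cfg, "A", "control", seed = 12)
  s2 <- simulate_subject(mod, cfg, "A", "control", seed = 12)
  expect_length(s1$trials, 3 * 30)
  expect_identical(s1$trials[[17]]$forces, s2$trials[[17]]$forces)

  blocks <- vapply(s1$trials, `[[`, 1L, "block")
  for (b in unique(blocks)) {
    trs <- s1$trials[blocks == b]
    key <- vapply(trs, function(t)
      paste(t$instructed_hand, t$instructed_finger, t$target_level), "")
    expect_length(trs, 30)
    expect_equal(max(table(key)), 1)  # every finger x level exactly once
    finger <- vapply(trs, function(t)
      paste0(t$instructed_hand, t$instructed_finger), "")
    expect_true(all(table(finger) == 3))
  }
})

test_that("cohorts have the right composition and per-subject determinism", {
  cfg <- cohort_config(n_patients = 3, n_controls = 2, blocks = 2, seed = 21)
  sim <- simulate_cohort(cfg)
  expect_length(sim$cohort$subjects, 5)
  groups <- vapply(sim$cohort$subjects, `[[`, "", "group")
  expect_equal(sum(groups == "patient"), 3)

  for (s in sim$cohort$subjects) {
    if (s$group == "patient") {
      sm <- parse_symptom_map(s$symptom_map)
      expect_gte(sum(sm$hand == "R"), 1)
    } else {
      expect_length(s$symptom_map, 0)
    }
  }

  # same master seed, different cohort composition: shared subject unchanged
  cfg2 <- cohort_config(n_patients = 1, n_controls = 2, blocks = 2, seed = 21)
  sim2 <- simulate_cohort(cfg2)
  expect_identical(sim2$cohort$subjects[[1]]$trials[[7]]$forces,
                   sim$cohort$subjects[[1]]$trials[[7]]$forces)

  all_con <- simulate_cohort(cohort_config(n_patients = 0, n_controls = 2,
                                           blocks = 2, seed = 5))
  expect_true(all(vapply(all_con$cohort$subjects,
                         function(s) length(s$symptom_map) == 0, TRUE)))
})
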