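test_that("finger pairs are classified by instructed-first symptom status", {
  m <- classify_finger_pairs(c("R-D3", "R-D4"), "R")
  expect_equal(m["D3", "D4"], "sym-sym")
  expect_equal(m["D2", "D3"], "asy-sym")
  expect_equal(m["D3", "D2"], "sym-asy")
  expect_equal(m["D1", "D2"], "asy-asy")
  expect_true(all(is.na(diag(m))))

  none <- classify_finger_pairs(character(), "R")
  expect_true(all(none[!is.na(none)] == "asy-asy"))
  all5 <- classify_finger_pairs(paste0("R-D", 1:5), "R")
  expect_true(all(all5[!is.na(all5)] == "sym-sym"))

  # swapping the pair order maps sym-asy <-> asy-sym and fixes the rest
  tm <- t(m)
  swap <- c("sym-sym" = "sym-sym", "asy-asy" = "asy-asy",
            "sym-asy" = "asy-sym", "asy-sym" = "sym-asy")
  expect_equal(unname(swap[m[!is.na(m)]]), tm[!is.na(tm)])

  # left-hand status is independent of right-hand symptoms
  l <- classify_finger_pairs(c("R-D3", "L-D1"), "L")
  expect_equal(l["D1", "D2"], "sym-asy")
  expect_equal(l["D3", "D2"], "asy-asy")
})

test_that("group comparison matches the closed-form pooled t", {
  set.seed(9)
  vals <- c(rnorm(4, -3.2, 0.3), rnorm(3, -3.6, 0.3))
  cells <- lapply(vals, function(v) matrix(v, 5, 5))
  names(cells) <- sprintf("S%d", 1:7)
  study <- fake_study(cells, c(rep("patient", 4), rep("control", 3)))

  got <- group_mean_comparison(study, "enslaving", "R")
  expect_equal(got$df, 5)
  expect_equal(got$t, oracle_pooled_t(vals[1:4], vals[5:7]),
               tolerance = 1e-10)
  expect_equal(unname(got$group_means),
               c(exp(mean(vals[1:4])), exp(mean(vals[5:7]))))
  # agreement with the standard library implementation
  ref <- stats::t.test(vals[1:4], vals[5:7], var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  same <- fake_study(cells[c(1, 1, 1, 1)],
                     c("patient", "patient", "control", "control"))
  names(same$fits) <- sprintf("T%d", 1:4)
  eq <- group_mean_comparison(same, "enslaving", "R")
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("pair-category ANOVA reproduces a brute-force SS decomposition", {
  maps <- demographics_symptom_maps()
  set.seed(10)
  cells <- lapply(seq_along(maps), function(i) {
    m <- matrix(rnorm(25, -3.5, 0.4), 5, 5)
    dimnames(m) <- list(paste0("D", 1:5), paste0("D", 1:5))
    m
  })
  names(cells) <- names(maps)
  study <- fake_study(cells, rep("patient", length(maps)),
                      symptom_maps = maps)
  got <- symptomatic_pair_anova(study, "R")

  obs <- got$observations
  expect_equal(table(obs$category)[["sym-sym"]], 6)   # six multi-digit patients
  expect_equal(got$df_between, 3)
  expect_equal(got$df_within, 35)                     # 39 obs - 4 categories

  # brute-force sums of squares from the observations
  grand <- mean(obs$value)
  ssb <- sum(tapply(obs$value, obs$category, function(v)
    length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(obs$value, obs$category, function(v)
    sum((v - mean(v))^2)))
  f_oracle <- (ssb / got$df_between) / (ssw / got$df_within)
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_equal(got$eta_squared, ssb / (ssb + ssw), tolerance = 1e-10)
  expect_true(got$eta_squared >= 0 && got$eta_squared <= 1)
  expect_equal(nrow(got$tukey), choose(4, 2))

  flat <- fake_study(lapply(cells, function(m) {m[] <- -3; m}),
                     rep("patient", length(maps)), symptom_maps = maps)
  eq <- symptomatic_pair_anova(flat, "R")
  expect_equal(eq$F, 0)
  expect_equal(eq$eta_squared, 0)
})

test_that("paired symptom contrasts match the closed-form paired t", {
  maps <- demographics_symptom_maps()
  set.seed(11)
  cells <- lapply(seq_along(maps), function(i)
    matrix(rnorm(25, -4.7, 0.3), 5, 5))
  names(cells) <- names(maps)
  study <- fake_study(cells, rep("patient", length(maps)),
                      symptom_maps = maps)

  got <- instructed_symptom_mirroring_test(study)
  expect_equal(got$df, 10)  # 11 patients, all partially symptomatic

  # closed-form oracle on the same per-patient means
  sym_m <- asy_m <- numeric(0)
  for (id in names(maps)) {
    symf <- paste0("D", 1:5) %in% sub("R-", "", grep("^R-", maps[[id]],
                                                     value = TRUE))
    cm <- cells[[id]]
    sym_m <- c(sym_m, mean(cm[symf, ]))
    asy_m <- c(asy_m, mean(cm[!symf, ]))
  }
  d <- sym_m - asy_m
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  ref <- stats::t.test(sym_m, asy_m, paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  md <- mirror_dystonia_test(study)
  expect_equal(md$df, 10)
  # a constant mirroring matrix cannot prefer symptomatic fingers
  const <- fake_study(lapply(cells, function(m) {m[] <- -4.7; m}),
                      rep("patient", length(maps)), symptom_maps = maps)
  expect_equal(mirror_dystonia_test(const)$t, 0)
  expect_equal(instructed_symptom_mirroring_test(const)$t, 0)
})

test_that("fully symptomatic patients are excluded from paired contrasts", {
  maps <- list(A = paste0("R-D", 1:5), B = c("R-D2"), C = c("R-D3"))
  set.seed(12)
  cells <- lapply(1:3, function(i) matrix(rnorm(25, -4.7, 0.3), 5, 5))
  names(cells) <- names(maps)
  study <- fake_study(cells, rep("patient", 3), symptom_maps = maps)
  expect_warning(got <- instructed_symptom_mirroring_test(study),
                 "all-or-none")
  expect_equal(got$df, 1)
})

test_that("demographics reproduce the published cohort summaries", {
  demo <- patient_demographics()
  expect_equal(nrow(demo), 11)
  maps <- demographics_symptom_maps(demo)
  multi_right <- sum(vapply(maps, function(m)
    sum(grepl("^R-", m)) >= 2, TRUE))
  expect_equal(multi_right, 6)
  left_involved <- sum(vapply(maps, function(m) any(grepl("^L-", m)), TRUE))
  expect_equal(left_involved, 2)

  demo$group <- "patient"
  ds <- demographic_summary(demo)
  tab <- ds$table
  expect_equal(tab$age_mean, 49.9, tolerance = 0.05)
  expect_equal(tab$duration_years_mean, 7.82, tolerance = 0.005)
  expect_equal(tab$duration_years_sd, 7.21, tolerance = 0.005)
  expect_equal(tab$severity_mean, 2.55, tolerance = 0.005)
  expect_equal(tab$severity_sd, 0.69, tolerance = 0.005)
  expect_null(ds$age_test)  # one group only

  single <- data.frame(group = c("patient", "control"), age = c(50, 40),
                       severity = c(3, NA))
  tab1 <- demographic_summary(single)$table
  expect_true(all(is.na(tab1$age_sd)))
})
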