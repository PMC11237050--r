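test_that("a noise-free subject has split-half reliability exactly 1", {
  sim <- sim_subject(seed = 14, blocks = 2, noise = FALSE)
  expect_equal(split_half_reliability(sim$subject, "enslaving", "R"), 1,
               tolerance = 1e-9)
  expect_equal(split_half_reliability(sim$subject, "mirroring", "R->L"), 1,
               tolerance = 1e-9)
})

test_that("reliability is invariant to which parity is called odd", {
  sim <- sim_subject(seed = 15, blocks = 4)
  r1 <- split_half_reliability(sim$subject, "enslaving", "R")
  flipped <- sim$subject
  for (i in seq_along(flipped$trials)) {
    flipped$trials[[i]]$block <- flipped$trials[[i]]$block + 1L
  }
  r2 <- split_half_reliability(flipped, "enslaving", "R")
  expect_equal(r2, r1, tolerance = 1e-12)

  only_odd <- sim$subject
  only_odd$trials <- Filter(function(t) t$block %% 2 == 1, only_odd$trials)
  expect_error(split_half_reliability(only_odd), "odd and one even")
})

test_that("group reliability pools on the Fisher-Z scale", {
  # hand-computed oracle for r = (0.8, 0.9)
  z <- atanh(c(0.8, 0.9))
  se <- sd(z) / sqrt(2)
  want_mean <- tanh(mean(z))
  want_ci <- tanh(mean(z) + c(-1.96, 1.96) * se)

  fake_subjects <- list(
    structure(list(subject_id = "a"), class = "subject_record"),
    structure(list(subject_id = "b"), class = "subject_record"))
  local_mocked_bindings(
    split_half_reliability = function(subject, kind, context) {
      c(a = 0.8, b = 0.9)[[subject$subject_id]]
    },
    .package = "findiv")
  got <- group_reliability(fake_subjects, "enslaving", "R")
  expect_equal(got$mean_r, want_mean, tolerance = 1e-12)
  expect_equal(got$ci, want_ci, tolerance = 1e-12)
  expect_true(all(got$ci >= -1 & got$ci <= 1))
  expect_lt(got$ci[1], got$ci[2])
})

test_that("degenerate equal correlations give a zero-width interval", {
  subs <- lapply(1:4, function(i)
    structure(list(subject_id = paste0("s", i)), class = "subject_record"))
  local_mocked_bindings(
    split_half_reliability = function(subject, kind, context) 0.9,
    .package = "findiv")
  got <- group_reliability(subs)
  expect_equal(got$mean_r, 0.9, tolerance = 1e-12)
  expect_equal(diff(got$ci), 0, tolerance = 1e-12)
})

test_that("identical patterns across subjects give r = 1, t = 0, p = 1", {
  base <- matrix(rnorm(25), 5, 5)
  cells <- rbind(as.vector(base), as.vector(base), as.vector(base),
                 as.vector(base))
  res <- crossval_similarity(cells, c("patient", "patient",
                                      "control", "control"))
  expect_equal(unname(res$r), rep(1, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2)
})

test_that("a control's similarity ignores its own cells (leave-one-out)", {
  set.seed(33)
  base <- rnorm(20, -3.5, 0.5)
  cells <- t(replicate(6, base + rnorm(20, 0, 0.2)))
  group <- c("patient", "patient", rep("control", 4))

  res1 <- crossval_similarity(cells, group)
  cells2 <- cells
  cells2[3, ] <- 5 + 3 * cells2[3, ]  # rescale one control's own pattern
  res2 <- crossval_similarity(cells2, group)
  # its own r is unchanged: the reference excludes it, and Pearson r is
  # invariant to an affine transform of the subject's own cells
  expect_equal(res2$r[3], res1$r[3], tolerance = 1e-12)
  # but the patients' r values change, because the control average they are
  # compared against now contains the outlier
  expect_false(isTRUE(all.equal(res2$r[1], res1$r[1])))
})

test_that("similarity df follows the two-group design", {
  set.seed(44)
  base <- rnorm(20, -3.5, 0.5)
  cells <- t(replicate(18, base + rnorm(20, 0, 0.3)))
  res <- crossval_similarity(cells, c(rep("patient", 11), rep("control", 7)))
  expect_equal(res$df, 16)
  expect_true(abs(res$mean_patient_r) <= 1)
})

test_that("zero-variance patterns are excluded with a warning", {
  set.seed(55)
  base <- rnorm(20)
  cells <- t(replicate(6, base + rnorm(20, 0, 0.2)))
  cells[4, ] <- 1  # constant pattern
  expect_warning(
    res <- crossval_similarity(cells, c("patient", "patient",
                                        rep("control", 4))),
    "zero-variance")
  expect_true(is.na(res$r[4]))
})

test_that("a pure gain offset does not separate pattern similarity", {
  # patients share the controls' pattern architecture, only shifted by a
  # constant log-slope (a magnitude difference); their similarity to the
  # control average must be statistically indistinguishable from controls'
  set.seed(66)
  ps <- replicate(40, {
    base <- rnorm(20, -3.5, 0.5)
    cells <- t(sapply(1:18, function(i) base + rnorm(20, 0, 0.25)))
    cells[1:11, ] <- cells[1:11, ] + 0.5
    crossval_similarity(cells, c(rep("patient", 11), rep("control", 7)))$p
  })
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
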