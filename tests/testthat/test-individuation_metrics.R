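test_that("exact linear data gives the exact origin slope", {
  expect_equal(robust_origin_slope(c(2, 4, 6), c(0.10, 0.20, 0.30)), 0.05)
  expect_equal(robust_origin_slope(1:5, rep(0, 5)), 0)
  expect_error(robust_origin_slope(c(1, 2), c(1, 2)), "at least 3")
  expect_error(robust_origin_slope(c(-1, -2, 0), c(1, 2, 3)), "<= 0")
})

test_that("an outlier is downweighted towards the oracle solution", {
  x <- c(1, 2, 3, 4)
  y <- c(0.03, 0.06, 0.09, 1.20)
  got <- robust_origin_slope(x, y)
  ols <- sum(x * y) / sum(x * x)
  expect_lt(got, ols)
  expect_equal(got, oracle_bisquare_slope(x, y), tolerance = 1e-6)
  expect_lt(abs(got - 0.03), 0.01)  # near the uncontaminated slope
})

test_that("the IRLS solver matches the brute-force oracle on random problems", {
  set.seed(2024)
  for (i in 1:100) {
    p <- random_slope_problem()
    got <- robust_origin_slope(p$x, p$y)
    want <- oracle_bisquare_slope(p$x, p$y)
    expect_lt(abs(got - want), 1e-6,
              label = sprintf("problem %d |impl - oracle|", i))
  }
})

test_that("slopes agree with an established robust regression fit", {
  skip_if_not_installed("MASS")
  set.seed(77)
  for (i in 1:10) {
    p <- random_slope_problem(n = 25)
    fit <- MASS::rlm(p$y ~ p$x - 1, psi = MASS::psi.bisquare, maxit = 100)
    expect_equal(robust_origin_slope(p$x, p$y), unname(coef(fit)),
                 tolerance = 0.01)
  }
})

test_that("robust slope is exactly scale-equivariant in y", {
  set.seed(12)
  p <- random_slope_problem(n = 20)
  b1 <- robust_origin_slope(p$x, p$y)
  b3 <- robust_origin_slope(p$x, 3 * p$y)
  expect_equal(b3, 3 * b1, tolerance = 1e-9)
})

test_that("log_slope floors non-positive slopes", {
  expect_equal(log_slope(1.0), 0)
  expect_equal(log_slope(0), log(1e-4))
  expect_equal(log_slope(-0.2), log(1e-4))
  expect_equal(log_slope(0.028), -3.5756, tolerance = 1e-4)
})

test_that("noise-free patterns recover uniform couplings in every cell", {
  cfg <- noise_free(cohort_config(distance_decay = 0, blocks = 2))
  mod <- uniform_model(e = 0.05, m = 0.006, config = cfg)
  sub <- simulate_subject(mod, cfg, "U1", "control", seed = 3)
  pt <- build_peak_table(sub)

  for (hand in c("L", "R")) {
    ep <- enslaving_pattern(pt, hand)
    expect_equal(sum(ep$valid), 20)
    expect_false(any(diag(ep$valid)))
    expect_equal(unname(ep$cells[ep$valid]), rep(log(0.05), 20),
                 tolerance = 1e-9)
    expect_true(all(ep$n_points[ep$valid] == 2 * 3))
  }
  for (hand in c("L", "R")) {
    mp <- mirroring_pattern(pt, hand)
    expect_equal(sum(mp$valid), 25)
    expect_equal(unname(mp$cells[mp$valid]), rep(log(0.006), 25),
                 tolerance = 1e-9)
  }
})

test_that("pairs with too few trials are flagged invalid", {
  sim <- sim_subject(seed = 9, blocks = 2, noise = FALSE)
  pt <- build_peak_table(sim$subject)
  pt_thin <- pt[!(pt$instructed_hand == "R" & pt$instructed_finger == "D2" &
                    pt$block == 1), ]
  pt_thin <- pt_thin[!(pt_thin$instructed_hand == "R" &
                         pt_thin$instructed_finger == "D2" &
                         pt_thin$target_level != 0.5), ]
  w <- testthat::capture_warnings(ep <- enslaving_pattern(pt_thin, "R"))
  expect_length(w, 4)  # the four cells of the thinned D2 row
  expect_match(w, "invalid", all = TRUE)
  expect_equal(sum(ep$valid), 16)  # the D2 row dropped out
})

test_that("mean pattern strength is the geometric mean of slopes", {
  cells <- matrix(log(0.046), 5, 5)
  p <- fake_pattern(cells)
  ms <- mean_pattern_strength(p)
  expect_equal(ms$strength, 0.046)
  expect_equal(ms$n_cells, 20)

  cells2 <- matrix(rep(c(log(0.01), log(0.04)), length.out = 25), 5, 5)
  cells2[1, 2] <- log(0.01); cells2[2, 1] <- log(0.04)
  two <- fake_pattern(cells2)
  two$valid[] <- FALSE
  two$valid[1, 2] <- two$valid[2, 1] <- TRUE
  ms2 <- mean_pattern_strength(two)
  expect_equal(ms2$mean_log_slope, -3.9120, tolerance = 1e-4)
  expect_equal(ms2$strength, 0.02)  # sqrt(0.01 * 0.04)

  none <- fake_pattern(cells)
  none$valid[] <- FALSE
  expect_error(mean_pattern_strength(none), "no valid cells")
})
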