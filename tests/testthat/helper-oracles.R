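# Independent oracles used across the suite.

# Brute-force bisquare IRLS oracle for the origin-constrained robust slope,
# written directly from the weight-function definition as a damped fixed-point
# iteration with a much tighter tolerance than the implementation under test.
oracle_bisquare_slope <- function(x, y, c_tuning = 4.685) {
  gmap <- function(b) {
    r <- y - b * x
    med <- stats::median(r)
    s <- stats::median(abs(r - med)) / 0.6745
    if (s == 0) return(sum(x * y) / sum(x * x))
    u <- r / (c_tuning * s)
    w <- numeric(length(u))
    inside <- abs(u) < 1
    w[inside] <- (1 - u[inside]^2)^2
    if (sum(w * x * x) == 0) return(b)
    sum(w * x * y) / sum(w * x * x)
  }
  b <- sum(x * y) / sum(x * x)  # unweighted origin LS start
  for (i in 1:10000) {
    b_new <- gmap(b)
    if (abs(b_new - b) < 1e-13 * max(1, abs(b))) return(b_new)
    b <- b_new
  }
  # non-convergent cycle around the fixed point: expand a bracket around
  # the last iterate and bisect gmap(b) - b
  hfun <- function(b) gmap(b) - b
  delta <- max(1e-7, 1e-5 * abs(b))
  while (delta < max(1, abs(b))) {
    lo <- b - delta; hi <- b + delta
    if (hfun(lo) * hfun(hi) < 0) {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (hfun(lo) * hfun(mid) <= 0) hi <- mid else lo <- mid
      }
      return((lo + hi) / 2)
    }
    delta <- delta * 2
  }
  b
}

# random origin-regression problem with optional gross outliers
random_slope_problem <- function(n = NULL) {
  n <- if (is.null(n)) sample(5:30, 1) else n
  slope <- stats::runif(1, 0.001, 0.2)
  x <- stats::runif(n, 1, 15)
  y <- slope * x + stats::rnorm(n, 0, 0.05)
  n_out <- sample(0:2, 1)
  if (n_out > 0) {
    idx <- sample(n, n_out)
    y[idx] <- y[idx] + stats::runif(n_out, 0.5, 3) * sample(c(-1, 1), n_out,
                                                            replace = TRUE)
  }
  list(x = x, y = y, slope = slope)
}

# textbook two-sample pooled-variance t
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n2))
}
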