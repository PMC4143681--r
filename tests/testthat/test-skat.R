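test_that("MAF-inverse weights follow the closed form and monotonicity", {
  expect_equal(madsen_browning_weights(0.5), 2)
  expect_equal(madsen_browning_weights(0.01), 1 / sqrt(0.01 * 0.99),
               tolerance = 1e-12)
  w <- madsen_browning_weights(c(0.01, 0.1))
  expect_gt(w[1], w[2])
  expect_error(madsen_browning_weights(c(0.1, 0)), "0, 0.5")
  expect_error(madsen_browning_weights(0.6), "0, 0.5")
  ## Beta(1,25) alternative is also decreasing on (0, 0.5]
  wb <- beta_maf_weights(c(0.005, 0.05, 0.4))
  expect_true(all(diff(wb) < 0))
})

test_that("null_score projects the intercept and estimates the scale", {
  y <- rep(3.2, 50)
  ns <- null_score(y, rep(1, 50))
  expect_equal(ns$r, rep(0, 50))
  set.seed(1)
  y <- rnorm(64)
  i <- rep(c(1, -1), 32)               # orthogonal to y's projection? no:
  y <- y - i * sum(i * y) / sum(i^2)   # force orthogonality
  expect_equal(null_score(y, i)$r, y)
  set.seed(2)
  y <- rnorm(1000)
  s2 <- null_score(y, rep(1, 1000))$sigma2
  expect_lt(abs(s2 - 1), 3 * sqrt(2 / 1000))
  expect_error(null_score(1, 1), "more than one")
  expect_error(null_score(c(1, 2), c(0, 0)), "zero norm")
})

test_that("Q statistic interpolates SKAT and burden", {
  ## scores s = (1, -1) with unit weights: rho 0 -> 2, rho 1 -> 0
  G <- cbind(c(1, 0, 0), c(0, 1, 0))
  r <- c(1, -1, 0)
  expect_equal(q_statistic(G, r, c(1, 1), 0), 2)
  expect_equal(q_statistic(G, r, c(1, 1), 1), 0)
  expect_equal(q_statistic(G, r, c(1, 1), 0.3), 0.7 * 2)
  ## one variant: rho-free
  G1 <- matrix(c(2, 1, 0), 3)
  qs <- vapply(c(0, 0.25, 1), function(rh) q_statistic(G1, r, 1.5, rh), 0)
  expect_equal(qs, rep(qs[1], 3))
  expect_equal(q_statistic(G, numeric(3), c(1, 1), 0.5), 0)
  expect_error(q_statistic(G, r, c(1, 1), 1.2), "rho")
})

test_that("single-variant regions degenerate to one test", {
  w <- white_region(n = 150, m = 1, seed = 3)
  fit <- skat_o(w$G, w$y, w$i, w$maf)
  expect_equal(fit$p_skat, fit$p_burden, tolerance = 1e-4)
  expect_equal(fit$p_skat, fit$p_skato, tolerance = 1e-4)
})

test_that("SKAT-O respects the min-p bracket and scale invariance", {
  grid <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)
  for (seed in 1:12) {
    w <- white_region(n = 120, m = 10, seed = seed)
    fit <- skat_o(w$G, w$y, w$i, w$maf, rho_grid = grid)
    minp <- min(fit$p_skat, fit$p_burden)
    expect_gt(fit$p_skato, 0)
    expect_lte(fit$p_skato, min(1, length(grid) * minp + 1e-6))
    expect_true(fit$rho_min %in% grid)
    scaled <- skat_o(w$G, w$y * 1e3, w$i, w$maf, rho_grid = grid)
    expect_equal(scaled$p_skat, fit$p_skat, tolerance = 1e-10)
    expect_equal(scaled$p_burden, fit$p_burden, tolerance = 1e-10)
    expect_equal(scaled$p_skato, fit$p_skato, tolerance = 1e-8)
  }
})

test_that("SKAT-O p-values are uniform under the white null", {
  set.seed(42)
  n <- 150
  reps <- 1500
  po <- numeric(reps)
  for (k in seq_len(reps)) {
    m <- sample(5:25, 1)
    maf <- runif(m, 0.005, 0.4)
    G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
    keep <- colSums(G) > 0
    G <- G[, keep, drop = FALSE]
    p <- colMeans(G) / 2
    po[k] <- skat_o(G, rnorm(n), rep(1, n), pmin(p, 1 - p))$p_skato
  }
  for (a in c(0.05, 0.01)) {
    se <- sqrt(a * (1 - a) / reps)
    expect_lt(abs(mean(po <= a) - a), 3.5 * se)
  }
  expect_gt(ks.test(po, "punif")$p.value, 0.001)
})

test_that("burden wins for equal-signed effects, SKAT for mixed signs", {
  set.seed(9)
  n <- 400
  m <- 12
  res <- replicate(60, {
    maf <- runif(m, 0.02, 0.1)
    G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
    p <- colMeans(G) / 2
    keep <- p > 0
    beta_same <- rep(0.35, m)
    beta_mix <- rep(c(0.45, -0.45), m / 2)
    y_same <- as.vector(G %*% beta_same) + rnorm(n)
    y_mix <- as.vector(G %*% beta_mix) + rnorm(n)
    f_same <- skat_o(G[, keep], y_same, rep(1, n), pmin(p, 1 - p)[keep])
    f_mix <- skat_o(G[, keep], y_mix, rep(1, n), pmin(p, 1 - p)[keep])
    c(same = f_same$p_burden <= f_same$p_skat,
      mix = f_mix$p_skat <= f_mix$p_burden)
  })
  expect_gt(mean(res["same", ]), 0.5)
  expect_gt(mean(res["mix", ]), 0.5)
})

test_that("the fixed-panel quadrature matches adaptive integration", {
  ## integrands of the SKAT-O level type: smooth monotone tail times the
  ## chi-square(1) density after the x = t^2 substitution
  lam <- exp(seq(0, -3, length.out = 12))
  for (qm in c(2, 6, 15)) {
    f <- function(t) 2 * t * pchisq(pmax(qm - 0.8 * t^2, 0) / mean(lam),
                                    df = 8) * dchisq(t^2, 1)
    gp <- glsskat:::gauss_panels(f, breaks = c(0, 1, 2.5, 4, 6, 8.5),
                                 n_nodes = 24)
    ad <- integrate(f, 0, 8.5, rel.tol = 1e-10, abs.tol = 1e-12,
                    subdivisions = 500L)$value
    expect_lt(abs(gp - ad), 1e-6)   # the kink at the clamp limits GL order
  }
  ## and the quadrature itself is exact for polynomials
  g <- function(t) 3 * t^5 - t^2 + 4
  gp <- glsskat:::gauss_panels(g, breaks = c(0, 2, 5), n_nodes = 8)
  expect_lt(abs(gp - integrate(g, 0, 5)$value), 1e-9)
})

test_that("region tests never re-filter by MAF: all supplied variants count", {
  w <- white_region(n = 150, m = 8, seed = 5)
  maf <- w$maf
  maf[1] <- 0.5                        # a common variant stays in
  fit <- skat_o(w$G, w$y, w$i, maf)
  expect_equal(fit$n_variants, ncol(w$G))
})
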