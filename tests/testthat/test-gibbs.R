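test_that("latent-response conditional matches hand-derived mean and variance", {
  set.seed(1)
  z <- sample_z(y_scaled = 2, err_var = 1, xb = 0, sigma2 = 1)
  expect_equal(attr(z, "var"), 0.5)
  expect_equal(attr(z, "mean"), 1)
  # zero measurement error pins z to the data
  z <- sample_z(2, 1e-12, 0, 1)
  expect_equal(attr(z, "mean"), 2, tolerance = 1e-9)
  expect_lt(attr(z, "var"), 1e-11)
  # vanishing biological variance pins z to the regression mean
  z <- sample_z(2, 1, 3, 1e-12)
  expect_equal(attr(z, "mean"), 3, tolerance = 1e-9)
})

test_that("coefficient conditional matches hand-derived moments and limits", {
  set.seed(2)
  X <- matrix(1, 2, 1)
  b <- sample_beta(z = c(1, 1), X, sigma2 = 1, delta = 0, tau = 1, c_mult = 1)
  expect_equal(attr(b, "cov")[1, 1], 1 / 3)
  expect_equal(attr(b, "mean"), 2 / 3)
  b <- sample_beta(c(0, 0), X, 1, 0, 1, 1)
  expect_equal(attr(b, "mean"), 0)
  # flat-prior limit recovers least squares
  set.seed(3)
  Xf <- cbind(1, c(-1, 1, -1, 1))
  zf <- rnorm(4)
  b <- sample_beta(zf, Xf, 1, c(1, 1), tau = 1e4, c_mult = 1)
  expect_equal(attr(b, "mean"), unname(coef(lm(zf ~ 0 + Xf))), tolerance = 1e-6)
})

test_that("variance conditional has the printed shape and scale", {
  set.seed(4)
  X <- matrix(1, 2, 1)
  s2 <- sample_sigma2(z = c(0, 0), X, beta = 0, delta = 0,
                      tau = 1, c_mult = 1, nu = 2.5, lam = 0.04)
  expect_equal(attr(s2, "shape"), 2.75)       # (n + p + nu)/2 = (2+1+2.5)/2
  expect_equal(attr(s2, "scale"), 0.05)       # z = X beta, beta = 0: nu*lam/2
  expect_gt(as.numeric(s2), 0)
  # beta contributes through D^-1
  s2 <- sample_sigma2(c(0.5, 0.5), X, 0.5, 0, tau = 0.5, c_mult = 1,
                      nu = 2.5, lam = 0.04)
  expect_equal(attr(s2, "scale"), 0.5 * (0.1 + 0.25 / 0.25))
})

test_that("inclusion conditional reduces to the prior, penalises nulls, accepts tails", {
  set.seed(5)
  d <- sample_delta(beta = 0.3, sigma2 = 1, tau = 0.1, c_mult = 1, prior_p = 0.37)
  expect_equal(attr(d, "prob"), 0.37, tolerance = 1e-12)
  d <- sample_delta(0, 1, 0.1, 4.25, 0.1)
  expect_equal(attr(d, "prob"), 0.1 / (0.1 + 4.25 * 0.9), tolerance = 1e-12)
  d <- sample_delta(50, 1, 0.1, 4.25, 0.1)
  expect_gt(attr(d, "prob"), 1 - 1e-6)
})

test_that("both engines follow the same RNG path and fixed seeds reproduce fits", {
  set.seed(10)
  n <- 8
  X <- cbind(parental = 1, cross = rep(c(1, -1), 4))
  y <- rnorm(n); ev <- runif(n, 0.05, 0.2)
  h <- braim_hyper(n_iter = 300L, burn_in = 100L)
  set.seed(99); a <- run_gibbs(y, ev, X, h, engine = "cpp")
  set.seed(99); b <- run_gibbs(y, ev, X, h, engine = "r")
  expect_identical(a$post_delta + 0L, b$post_delta + 0L)
  expect_equal(a$post_beta, b$post_beta, tolerance = 1e-12)
  expect_equal(a$post_sigma2, b$post_sigma2, tolerance = 1e-12)
  set.seed(99); a2 <- run_gibbs(y, ev, X, h, engine = "cpp")
  expect_identical(a$post_beta, a2$post_beta)
})

test_that("sampler agrees with the exhaustive-configuration oracle", {
  # n = 4, p = 2, negligible measurement error: the brute-force enumeration
  # of all inclusion configurations is exact
  set.seed(21)
  X <- cbind(parental = 1, cross = c(1, -1, 1, -1))
  for (y in list(c(1.2, 0.8, 1.1, 0.9), rnorm(4))) {
    y <- y / sd(y)
    h <- braim_hyper(n_iter = 30000L, burn_in = 2000L)
    oracle <- exact_spike_slab_posterior(y, X, h)
    set.seed(77)
    g <- run_gibbs(y, rep(1e-8, 4), X, h)
    for (i in 1:2) {
      se <- max(mcse(g$post_delta[, i]), 0.01)
      expect_lt(abs(g$pp[i] - oracle$pp[i]), 3 * se)
      se_b <- max(mcse(g$post_beta[, i]), 0.01)
      expect_lt(abs(g$beta_mean[i] - oracle$beta_mean[i]), 3 * se_b)
    }
  }
})

test_that("with zero measurement error and slab-only inclusion the posterior is conjugate", {
  set.seed(22)
  X <- cbind(parental = 1, cross = c(1, 1, -1, -1, 1, -1))
  y <- rnorm(6); y <- y / sd(y)
  h <- braim_hyper(n_iter = 40000L, burn_in = 2000L)
  closed <- conjugate_limit_posterior(y, X, h)
  set.seed(55)
  g <- run_gibbs(y, rep(1e-8, 6), X, h, fix_delta = c(1L, 1L))
  for (i in 1:2) {
    se <- max(mcse(g$post_beta[, i]), 0.005)
    expect_lt(abs(g$beta_mean[i] - closed$beta_mean[i]), 3 * se)
    expect_equal(g$beta_sd[[i]], sqrt(closed$beta_cov[i, i]), tolerance = 0.1)
  }
})

test_that("chain invariants hold: positive variances, PPs in range", {
  set.seed(23)
  X <- cbind(parental = 1, cross = rep(c(1, -1), 6),
             sex = rep(c(1, 1, -1, -1), 3))
  y <- rnorm(12); ev <- runif(12, 0.01, 0.5)
  g <- run_gibbs(y / sd(y), ev, X, braim_hyper(n_iter = 1000L, burn_in = 200L))
  expect_true(all(g$post_sigma2 > 0))
  expect_true(all(g$pp >= 0 & g$pp <= 1))
  expect_true(all(g$post_delta %in% c(0L, 1L)))
})

test_that("per-transcript RNG streams make fits order-independent", {
  sim <- small_cohort(n_transcripts = 4, n_imprinted = 2)
  h <- fast_hyper(n_iter = 400L, burn_in = 100L)
  f1 <- braim_fit(sim$posteriors, sim$design, h)
  shuffled <- dplyr::arrange(sim$posteriors, dplyr::desc(transcript_id))
  f2 <- braim_fit(shuffled, sim$design, h)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(f1), transcript_id, effect),
    dplyr::arrange(tibble::as_tibble(f2), transcript_id, effect)
  )
})

test_that("a null parental effect rarely crosses the calling cutoff", {
  # replicate-level check of calibration under the null: fit many null
  # transcripts and require < 5% of parental PPs above 0.95
  sim <- small_cohort(n_transcripts = 60, n_imprinted = 0, seed = 303,
                      n_per_block = 6, s_draws = 20)
  fit <- braim_fit(sim$posteriors, sim$design,
                   braim_hyper(n_iter = 4000L, burn_in = 500L, seed = 17L))
  pp_par <- dplyr::filter(tibble::as_tibble(fit), effect == "parental")$pp
  expect_gte(mean(pp_par < 0.95), 0.95)
})
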