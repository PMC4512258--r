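# Independent brute-force oracle for the spike-and-slab regression in the
# zero-measurement-error limit. Enumerates all 2^p inclusion configurations;
# for each, the response marginal (z and beta and sigma^2 integrated out) is
# a multivariate t:
#   y | delta ~ t_nu(0, lambda * (X D_delta X' + I)),
# because y | sigma2, delta ~ N(0, sigma2 (X D X' + I)) and
# sigma2 ~ IG(nu/2, nu*lambda/2). The conditional coefficient mean
# (X'X + D^-1)^-1 X'y does not depend on sigma2, so the overall posterior
# mean of beta is the model-averaged mixture of these.
exact_spike_slab_posterior <- function(y, X, hyper) {
  n <- length(y); p <- ncol(X)
  tau <- rep(hyper$tau, length.out = p)
  cm <- rep(hyper$c_mult, length.out = p)
  pp_prior <- rep(hyper$prior_p, length.out = p)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- numeric(nrow(configs))
  bmeans <- matrix(0, nrow(configs), p)
  for (k in seq_len(nrow(configs))) {
    delta <- configs[k, ]
    d <- (tau * cm^delta)^2
    M <- X %*% diag(d, p) %*% t(X) + diag(n)
    S <- hyper$lam * M
    # multivariate t log density at 0 mean, df = nu
    Si <- solve(S)
    q <- drop(t(y) %*% Si %*% y)
    logm <- lgamma((hyper$nu + n) / 2) - lgamma(hyper$nu / 2) -
      (n / 2) * log(hyper$nu * pi) - 0.5 * determinant(S)$modulus -
      ((hyper$nu + n) / 2) * log1p(q / hyper$nu)
    logprior <- sum(delta * log(pp_prior) + (1 - delta) * log(1 - pp_prior))
    logw[k] <- logm + logprior
    A <- crossprod(X) + diag(1 / d, p)
    bmeans[k, ] <- solve(A, crossprod(X, y))
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  list(
    pp = drop(t(configs) %*% w),
    beta_mean = drop(t(bmeans) %*% w),
    weights = w, configs = configs
  )
}

# conjugate closed form with delta fixed at all-ones and E -> 0:
# beta | y ~ (marginal over sigma2) with mean (X'X + D^-1)^-1 X'y and
# covariance E[sigma2 | y] (X'X + D^-1)^-1, where
# sigma2 | y ~ IG((n + nu)/2, (nu lambda + y' M^-1 y)/2), M = X D X' + I.
conjugate_limit_posterior <- function(y, X, hyper) {
  n <- length(y); p <- ncol(X)
  tau <- rep(hyper$tau, length.out = p)
  cm <- rep(hyper$c_mult, length.out = p)
  d <- (tau * cm)^2
  A <- crossprod(X) + diag(1 / d, p)
  M <- X %*% diag(d, p) %*% t(X) + diag(n)
  q <- drop(t(y) %*% solve(M, y))
  e_sigma2 <- (hyper$nu * hyper$lam + q) / (n + hyper$nu - 2)
  list(
    beta_mean = drop(solve(A, crossprod(X, y))),
    beta_cov = e_sigma2 * solve(A),
    e_sigma2 = e_sigma2
  )
}

# batch-means Monte-Carlo standard error for an autocorrelated chain
mcse <- function(x, n_batches = 50) {
  n <- length(x)
  b <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  \(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
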