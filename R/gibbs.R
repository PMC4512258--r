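#' Conditional draw of the latent true response z
#'
#' The observed scaled response \eqn{\hat y'} equals the latent biological
#' response z plus measurement noise with known diagonal covariance
#' E = diag(err_var). Conditionally on the regression mean \eqn{X\beta} and
#' biological variance \eqn{\sigma^2}, each z_j is normal with precision
#' \eqn{1/e_j + 1/\sigma^2} — a precision-weighted compromise between the
#' data and the regression fit:
#' \deqn{\Lambda_z = (E^{-1} + \Sigma^{-1})^{-1}, \quad
#'       \mu_z = \Lambda_z(\Sigma^{-1}X\beta + E^{-1}\hat y').}
#' Both matrices are diagonal, so the draw is elementwise.
#'
#' @param y_scaled Length-n scaled response.
#' @param err_var Length-n measurement-error variances (> 0).
#' @param xb Length-n current regression mean \eqn{X\beta}.
#' @param sigma2 Current biological variance (> 0).
#' @return Length-n draw of z. The conditional mean and variance are attached
#'   as attributes `"mean"` and `"var"` for diagnostics.
#' @export
sample_z <- function(y_scaled, err_var, xb, sigma2) {
  lam <- 1 / (1 / err_var + 1 / sigma2)
  mu <- lam * (xb / sigma2 + y_scaled / err_var)
  z <- mu + sqrt(lam) * rnorm(length(mu))
  attr(z, "mean") <- mu
  attr(z, "var") <- lam
  z
}

#' Conditional draw of the regression coefficients beta
#'
#' Given the latent response z, the coefficients have the conjugate normal
#' conditional of a linear regression with the sigma-scaled spike-and-slab
#' prior \eqn{\beta \mid \sigma^2, \delta \sim N(0, \sigma^2 D_\delta)} where
#' \eqn{D_\delta = \mathrm{diag}((\tau_i c_i^{\delta_i})^2)}:
#' \deqn{\Lambda_\beta = (X^T\Sigma^{-1}X + (\sigma^2 D_\delta)^{-1})^{-1},
#'       \quad \mu_\beta = \Lambda_\beta X^T\Sigma^{-1}z,}
#' with \eqn{\Sigma = \sigma^2 I}.
#'
#' @param z Length-n latent response.
#' @param X n-by-p design matrix.
#' @param sigma2 Current biological variance.
#' @param delta Length-p 0/1 inclusion vector.
#' @param tau,c_mult Spike scale and slab multiplier, length 1 or p.
#' @return Length-p draw with attributes `"mean"` and `"cov"`.
#' @export
sample_beta <- function(z, X, sigma2, delta, tau, c_mult) {
  p <- ncol(X)
  tau <- expand_hyper(tau, p, "tau")
  c_mult <- expand_hyper(c_mult, p, "c_mult")
  d <- (tau * c_mult^delta)^2
  prec <- crossprod(X) / sigma2
  diag(prec) <- diag(prec) + 1 / (sigma2 * d)
  R <- chol(prec)                       # R'R = precision
  mu <- backsolve(R, backsolve(R, crossprod(X, z) / sigma2, transpose = TRUE))
  beta <- drop(mu) + backsolve(R, rnorm(p))
  attr(beta, "mean") <- drop(mu)
  attr(beta, "cov") <- chol2inv(R)
  beta
}

#' Conditional draw of the biological variance sigma^2
#'
#' With the conjugate IG(\eqn{\nu/2, \nu\lambda/2}) prior and the sigma-scaled
#' coefficient prior, the conditional is
#' \deqn{\sigma^2 \mid z, \beta, \delta \sim
#'   \mathrm{IG}\!\left(\tfrac{n+p+\nu}{2},\;
#'   \tfrac12\left[\nu\lambda + (z - X\beta)^T(z - X\beta) +
#'   \beta^T D_\delta^{-1}\beta\right]\right).}
#' The shape is constant across sweeps; only the scale moves.
#'
#' @inheritParams sample_beta
#' @param beta Length-p current coefficients.
#' @param nu,lam IG hyperparameters.
#' @return A positive scalar draw with attributes `"shape"` and `"scale"`.
#' @export
sample_sigma2 <- function(z, X, beta, delta, tau, c_mult, nu, lam) {
  p <- ncol(X)
  tau <- expand_hyper(tau, p, "tau")
  c_mult <- expand_hyper(c_mult, p, "c_mult")
  d <- (tau * c_mult^delta)^2
  resid <- z - drop(X %*% beta)
  shape <- (length(z) + p + nu) / 2
  scale <- 0.5 * (nu * lam + sum(resid^2) + sum(beta^2 / d))
  s2 <- 1 / rgamma(1, shape = shape, rate = scale)
  attr(s2, "shape") <- shape
  attr(s2, "scale") <- scale
  s2
}

#' Conditional draw of the inclusion indicators delta
#'
#' Each indicator is Bernoulli with success probability
#' \deqn{P(\delta_i = 1) = \frac{p_i}{p_i + R_i (1 - p_i)}, \quad
#'   R_i = \frac{N(\beta_i; 0, \sigma^2\tau_i^2)}
#'              {N(\beta_i; 0, \sigma^2 (c_i\tau_i)^2)},}
#' the spike/slab density ratio at the current coefficient. The ratio is
#' computed in log space and the probability clamped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]}. At \eqn{\beta_i = 0} the ratio equals
#' \eqn{c_i}, so a null coefficient is included with probability well below
#' its prior.
#'
#' @inheritParams sample_sigma2
#' @param prior_p Prior inclusion probability, length 1 or p.
#' @return Length-p 0/1 vector with attribute `"prob"` (the Bernoulli
#'   probabilities).
#' @export
sample_delta <- function(beta, sigma2, tau, c_mult, prior_p) {
  p <- length(beta)
  tau <- expand_hyper(tau, p, "tau")
  c_mult <- expand_hyper(c_mult, p, "c_mult")
  prior_p <- expand_hyper(prior_p, p, "prior_p")
  # log R_i = log c_i - beta_i^2 (1 - 1/c_i^2) / (2 sigma^2 tau_i^2)
  log_ratio <- log(c_mult) - beta^2 * (1 - 1 / c_mult^2) / (2 * sigma2 * tau^2)
  prob <- 1 / (1 + exp(log_ratio + log1p(-prior_p) - log(prior_p)))
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  delta <- as.integer(runif(p) < prob)
  attr(delta, "prob") <- prob
  delta
}

#' Run the Gibbs sampler for one transcript
#'
#' Iterates the four conditional draws z -> beta -> sigma^2 -> delta starting
#' from the data-centred, prior-neutral state z = \eqn{\hat y'}, beta = 0,
#' sigma^2 = 1, delta = 0, retains the post-burn-in draws, and reports each
#' effect's posterior inclusion probability (PP) as the mean of its retained
#' delta draws. Two engines are available: the compiled chain (default) and a
#' pure-R reference chain; both consume R's RNG stream in the identical
#' order, so under the same seed they follow the same draw path and agree to
#' floating-point rounding.
#'
#' @param y_scaled Length-n scaled response (unit standard deviation).
#' @param err_var Length-n scaled measurement-error variances (> 0).
#' @param X n-by-p design matrix with named columns.
#' @param hyper A [braim_hyper()] object.
#' @param fix_delta Optional length-p 0/1 vector; when supplied the inclusion
#'   indicators are held fixed (useful for conjugate-limit diagnostics).
#' @param keep_draws Retain the full beta and sigma^2 chains (default TRUE).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @return A list of class `"braim_gibbs"`: `beta_mean`, `beta_sd`, `pp`
#'   (named per effect), `sigma2_mean`, and, when `keep_draws`, matrices
#'   `post_beta` (retained x p), `post_delta` and vector `post_sigma2`.
#' @export
run_gibbs <- function(y_scaled, err_var, X, hyper = braim_hyper(),
                      fix_delta = NULL, keep_draws = TRUE,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- length(y_scaled); p <- ncol(X)
  stopifnot(nrow(X) == n, length(err_var) == n, all(err_var > 0))
  tau <- expand_hyper(hyper$tau, p, "tau")
  c_mult <- expand_hyper(hyper$c_mult, p, "c_mult")
  prior_p <- expand_hyper(hyper$prior_p, p, "prior_p")
  if (!is.null(fix_delta)) {
    stopifnot(length(fix_delta) == p, all(fix_delta %in% c(0L, 1L)))
  }
  res <- if (engine == "cpp") {
    gibbs_chain_cpp(y_scaled, err_var, X, tau, c_mult, hyper$nu, hyper$lam,
                    prior_p, hyper$n_iter, hyper$burn_in,
                    if (is.null(fix_delta)) integer(0) else as.integer(fix_delta))
  } else {
    gibbs_chain_r(y_scaled, err_var, X, tau, c_mult, hyper$nu, hyper$lam,
                  prior_p, hyper$n_iter, hyper$burn_in, fix_delta)
  }
  res$sigma2 <- as.numeric(res$sigma2)
  effects <- colnames(X)
  out <- list(
    beta_mean = setNames(colMeans(res$beta), effects),
    beta_sd = setNames(apply(res$beta, 2, stats::sd), effects),
    pp = setNames(colMeans(res$delta), effects),
    sigma2_mean = mean(res$sigma2),
    n = n, effects = effects, hyper = hyper
  )
  if (keep_draws) {
    colnames(res$beta) <- effects
    colnames(res$delta) <- effects
    out$post_beta <- res$beta
    out$post_delta <- res$delta
    out$post_sigma2 <- res$sigma2
  }
  structure(out, class = "braim_gibbs")
}

# pure-R reference chain; RNG call order mirrors the compiled chain exactly
gibbs_chain_r <- function(y, evar, X, tau, c_mult, nu, lam, prior_p,
                          n_iter, burn_in, fix_delta = NULL) {
  n <- length(y); p <- ncol(X)
  keep <- n_iter - burn_in
  beta_out <- matrix(0, keep, p)
  delta_out <- matrix(0L, keep, p)
  s2_out <- numeric(keep)
  z <- y; beta <- rep(0, p); s2 <- 1
  delta <- if (is.null(fix_delta)) rep(0L, p) else as.integer(fix_delta)
  for (it in seq_len(n_iter)) {
    z <- sample_z(y, evar, drop(X %*% beta), s2)
    beta <- sample_beta(z, X, s2, delta, tau, c_mult)
    s2 <- as.numeric(sample_sigma2(z, X, beta, delta, tau, c_mult, nu, lam))
    if (is.null(fix_delta)) {
      delta <- sample_delta(beta, s2, tau, c_mult, prior_p)
    }
    if (it > burn_in) {
      beta_out[it - burn_in, ] <- beta
      delta_out[it - burn_in, ] <- delta
      s2_out[it - burn_in] <- s2
    }
  }
  list(beta = beta_out, delta = delta_out, sigma2 = s2_out)
}

#' @export
print.braim_gibbs <- function(x, ...) {
  cat("<braim_gibbs> n =", x$n, "\n")
  print(round(rbind(beta_mean = x$beta_mean, beta_sd = x$beta_sd, pp = x$pp), 4))
  invisible(x)
}

#' Fit the allelic-imbalance model to every transcript of a cohort
#'
#' Builds the scaled response set for the requested mode and age subset,
#' derives an independent RNG stream per transcript from `hyper$seed` and the
#' transcript id (so results do not depend on fitting order), and runs the
#' Gibbs sampler on each fit-able transcript.
#'
#' @param posteriors A posterior-draw tibble (see [read_posterior_table()]).
#' @param design A sample-design tibble.
#' @param hyper A [braim_hyper()] object; `hyper$seed` seeds the fit.
#' @param mode Response mode, see [build_response()].
#' @param ages Optional subset of `c("P8", "P60")`; when only one age is kept
#'   the age column is dropped from the design matrix automatically.
#' @param floor_c TPM floor.
#' @param stringent_cutoff Optional mean-ln(TPM) expression filter, see
#'   [build_response_set()].
#' @param keep_draws Retain full chains on each transcript (memory-heavy for
#'   large cohorts; default FALSE).
#' @param engine Gibbs engine, `"cpp"` or `"r"`.
#' @param response_set Optional precomputed [build_response_set()] result;
#'   skips rebuilding when the same cohort is refitted repeatedly (as in the
#'   sensitivity analysis). `posteriors`, `mode`, `ages`, `floor_c` and
#'   `stringent_cutoff` are ignored when supplied.
#' @return A tibble of class `"braim_fit"` with one row per transcript and
#'   effect: `transcript_id`, `gene_id`, `effect`, `beta_mean`, `beta_sd`,
#'   `pp`, `sigma2_mean`, `scale_sd`, `n`. Skipped (constant-response)
#'   transcripts are recorded in attribute `"skipped"`; per-transcript chains
#'   (when kept) in attribute `"draws"`.
#' @export
braim_fit <- function(posteriors, design, hyper = braim_hyper(),
                      mode = "diff", ages = NULL, floor_c = 0.01,
                      stringent_cutoff = NULL, keep_draws = FALSE,
                      engine = "cpp", response_set = NULL) {
  rs <- response_set %||%
    build_response_set(posteriors, design, mode = mode, floor_c = floor_c,
                       ages = ages, stringent_cutoff = stringent_cutoff)
  if (!is.null(response_set)) mode <- attr(response_set, "mode") %||% mode
  design_used <- design |>
    dplyr::filter(.data$sample_id %in% attr(rs, "sample_ids")) |>
    dplyr::arrange(match(.data$sample_id, attr(rs, "sample_ids")))
  factors <- c("cross", "sex", "age")
  factors <- factors[purrr::map_int(factors, \(f) dplyr::n_distinct(design_used[[f]])) > 1]
  X <- build_design_matrix(design_used, factors)

  fitted <- rs |> dplyr::filter(!.data$skipped)
  draws <- if (keep_draws) vector("list", nrow(fitted)) else NULL
  rows <- vector("list", nrow(fitted))
  for (i in seq_len(nrow(fitted))) {
    id <- fitted$transcript_id[i]
    withr::with_seed(transcript_seed(hyper$seed, id), {
      g <- run_gibbs(fitted$y_scaled[[i]], fitted$err_var_scaled[[i]], X,
                     hyper, keep_draws = keep_draws, engine = engine)
    })
    rows[[i]] <- tibble::tibble(
      transcript_id = id, gene_id = fitted$gene_id[i],
      effect = g$effects, beta_mean = unname(g$beta_mean),
      beta_sd = unname(g$beta_sd), pp = unname(g$pp),
      sigma2_mean = g$sigma2_mean, scale_sd = fitted$scale_sd[i],
      n = fitted$n[i]
    )
    if (keep_draws) draws[[i]] <- g
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      transcript_id = character(), gene_id = character(), effect = character(),
      beta_mean = double(), beta_sd = double(), pp = double(),
      sigma2_mean = double(), scale_sd = double(), n = integer()
    )
  }
  if (keep_draws) names(draws) <- fitted$transcript_id
  structure(
    out,
    class = c("braim_fit", class(tibble::tibble()))
    , hyper = hyper, mode = mode, ages = ages, factors = colnames(X)
    , skipped = rs$transcript_id[rs$skipped]
    , draws = draws
  )
}

#' @describeIn braim_fit Per-effect tidy summary (the fit table itself,
#'   without attributes).
#' @param x A `braim_fit` object.
#' @param ... Unused.
#' @method tidy braim_fit
#' @export
tidy.braim_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn braim_fit One row per transcript: parental-effect summary plus
#'   the largest non-parental PP.
#' @method glance braim_fit
#' @export
glance.braim_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$transcript_id, .data$gene_id) |>
    dplyr::summarise(
      parental_beta = .data$beta_mean[.data$effect == "parental"],
      parental_pp = .data$pp[.data$effect == "parental"],
      max_other_pp = suppressWarnings(max(.data$pp[.data$effect != "parental"])),
      sigma2_mean = .data$sigma2_mean[1],
      scale_sd = .data$scale_sd[1],
      n = .data$n[1],
      .groups = "drop"
    )
}

#' @describeIn braim_fit Histograms of the per-effect posterior probabilities
#'   across transcripts.
#' @param object A `braim_fit` object.
#' @method autoplot braim_fit
#' @export
autoplot.braim_fit <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pp)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$effect)) +
    ggplot2::labs(x = "posterior probability of inclusion",
                  y = "transcripts") +
    ggplot2::theme_minimal()
}
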