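#' Balanced reciprocal-cross sample design
#'
#' The canonical study design: every cross x sex x age combination (F1i/F1r,
#' male/female, P8/P60) replicated `n_per_block` times, 8 blocks in total —
#' 48 samples at the default of six replicates per block.
#'
#' @param n_per_block Replicates per factor block (default 6).
#' @return A sample-design tibble (see [read_design()]).
#' @export
sim_design <- function(n_per_block = 6) {
  grid <- tidyr::expand_grid(
    cross = c("F1i", "F1r"), sex = c("male", "female"), age = c("P8", "P60"),
    rep = seq_len(n_per_block)
  )
  grid |>
    dplyr::mutate(sample_id = sprintf("s%02d", dplyr::row_number())) |>
    dplyr::select("sample_id", "cross", "sex", "age")
}

#' Transcript specifications for a synthetic cohort
#'
#' Generates per-transcript ground-truth parameters: a subset of
#' `n_imprinted` transcripts receives a strong parental effect with absolute
#' size drawn uniformly from `[beta_min, beta_max]` on the log-ratio scale
#' (random sign); all others are null. The defaults mirror the recovery
#' conditions used throughout the package's validation: 500 transcripts of
#' which 50 are imprinted with |beta| >= 1, biological variance 0.25,
#' per-draw measurement standard deviation 0.1, and 100 posterior draws per
#' sample.
#'
#' @param n_transcripts Total transcripts.
#' @param n_imprinted How many receive a nonzero parental effect.
#' @param beta_min,beta_max Range of the absolute parental effect.
#' @param sigma2_true Biological variance of the log-ratio across samples.
#' @param meas_sd Per-draw measurement standard deviation on the log scale.
#' @param s_draws Posterior draws per sample and allele.
#' @param base_log_tpm_mean,base_log_tpm_sd Distribution of each
#'   transcript's baseline log expression.
#' @param seed Optional seed (local to this call).
#' @return A tibble of transcript specs with one gene per transcript.
#' @export
sim_transcript_specs <- function(n_transcripts = 500, n_imprinted = 50,
                                 beta_min = 1, beta_max = 3,
                                 sigma2_true = 0.25, meas_sd = 0.1,
                                 s_draws = 100, base_log_tpm_mean = 2,
                                 base_log_tpm_sd = 1, seed = NULL) {
  gen <- function() {
    idx <- seq_len(n_transcripts)
    beta_par <- numeric(n_transcripts)
    imp <- head(idx, n_imprinted)
    beta_par[imp] <- runif(n_imprinted, beta_min, beta_max) *
      sample(c(-1, 1), n_imprinted, replace = TRUE)
    tibble::tibble(
      transcript_id = sprintf("tx%04d", idx),
      gene_id = sprintf("g%04d", idx),
      base_log_tpm = rnorm(n_transcripts, base_log_tpm_mean, base_log_tpm_sd),
      beta_parental = beta_par,
      beta_cross = 0, beta_sex = 0, beta_age = 0,
      sigma2_true = sigma2_true, meas_sd = meas_sd,
      s_draws = as.integer(s_draws)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate an allele-specific posterior-draw cohort
#'
#' The generative mirror of the model being fitted. For each transcript and
#' sample, a true log-ratio is drawn around the design-determined mean:
#' \deqn{d_j \sim N(x_j^T\beta_{true},\ \sigma^2_{true}),}
#' placed symmetrically around the baseline so overall expression is
#' unconfounded with bias (paternal true log-TPM = base + d/2, maternal =
#' base - d/2). Each allele then emits `s_draws` lognormal posterior draws,
#' `exp(true log-TPM + N(0, meas_sd^2)) - floor_c` clamped at zero, which
#' emulates the spread of expression-estimation posteriors; the detection
#' floor applied downstream recovers exactly `floor_c` for unexpressed
#' draws (the subtraction makes the round trip through `log(tpm + floor_c)`
#' exact).
#'
#' @param specs Transcript specs from [sim_transcript_specs()] (columns
#'   `transcript_id`, `gene_id`, `base_log_tpm`, `beta_parental`,
#'   `beta_cross`, `beta_sex`, `beta_age`, `sigma2_true`, `meas_sd`,
#'   `s_draws`).
#' @param design A sample-design tibble, e.g. [sim_design()].
#' @param floor_c TPM floor used downstream.
#' @param seed Optional seed (local to this call).
#' @return A list with `posteriors` (long draw tibble) and `truth` (per
#'   transcript: true effects, true paternal fraction, `is_imprinted`).
#' @export
simulate_cohort <- function(specs, design, floor_c = 0.01, seed = NULL) {
  gen <- function() {
    X <- build_design_matrix(design,
      factors = intersect(c("cross", "sex", "age"),
                          names(design)[purrr::map_lgl(design, \(x) dplyr::n_distinct(x) > 1)]))
    n <- nrow(design)
    rows <- purrr::map(seq_len(nrow(specs)), function(t) {
      sp <- specs[t, ]
      beta <- c(sp$beta_parental,
                c(cross = sp$beta_cross, sex = sp$beta_sex,
                  age = sp$beta_age)[colnames(X)[-1]])
      mu_d <- drop(X %*% beta)
      d <- rnorm(n, mu_d, sqrt(sp$sigma2_true))
      log_pat <- sp$base_log_tpm + d / 2
      log_mat <- sp$base_log_tpm - d / 2
      S <- sp$s_draws
      draw_one <- function(log_tpm, allele) {
        noise <- matrix(rnorm(S * n, 0, sp$meas_sd), nrow = S)
        tpm <- pmax(exp(sweep(noise, 2, log_tpm, `+`)) - floor_c, 0)
        tibble::tibble(
          transcript_id = sp$transcript_id, gene_id = sp$gene_id,
          sample_id = rep(design$sample_id, each = S), allele = allele,
          draw_index = rep(seq_len(S), times = n), tpm = as.vector(tpm)
        )
      }
      dplyr::bind_rows(draw_one(log_pat, "paternal"),
                       draw_one(log_mat, "maternal"))
    })
    truth <- specs |>
      dplyr::transmute(
        .data$transcript_id, .data$gene_id,
        beta_parental = .data$beta_parental, beta_cross = .data$beta_cross,
        beta_sex = .data$beta_sex, beta_age = .data$beta_age,
        true_paternal_fraction = plogis(.data$beta_parental),
        is_imprinted = .data$beta_parental != 0
      )
    list(posteriors = dplyr::bind_rows(rows), truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Split one transcript into two read-ambiguous isoforms
#'
#' Replaces a transcript's draws by two isoforms that share its reads: in
#' every sample and allele, draw s of the pair is `(f_s, 1 - f_s)` times the
#' original draw, with the allocation fraction `f_s` varying across draws.
#' The two isoforms' posteriors are strongly anti-correlated while their sum
#' reproduces the original — the signature the transcript combiner detects.
#'
#' @param posteriors A posterior-draw tibble.
#' @param transcript_id Which transcript to split.
#' @param mean_fraction Mean allocation to the first isoform.
#' @param fraction_sd Across-draw standard deviation of the allocation.
#' @param seed Optional seed.
#' @return The posterior tibble with the transcript replaced by
#'   `<id>_iso1` / `<id>_iso2` (same gene).
#' @export
simulate_isoform_ambiguity <- function(posteriors, transcript_id,
                                       mean_fraction = 0.5,
                                       fraction_sd = 0.25, seed = NULL) {
  gen <- function() {
    target <- dplyr::filter(posteriors, .data$transcript_id == !!transcript_id)
    stopifnot(nrow(target) > 0)
    rest <- dplyr::filter(posteriors, .data$transcript_id != !!transcript_id)
    # one allocation per (sample, draw), shared between alleles so the pair
    # stays identical across alleles
    alloc <- target |>
      dplyr::distinct(.data$sample_id, .data$draw_index) |>
      dplyr::mutate(f = pmin(pmax(
        rnorm(dplyr::n(), mean_fraction, fraction_sd), 0.02), 0.98))
    target <- dplyr::left_join(target, alloc, by = c("sample_id", "draw_index"))
    iso1 <- dplyr::mutate(target,
                          transcript_id = paste0(!!transcript_id, "_iso1"),
                          tpm = .data$tpm * .data$f, f = NULL)
    iso2 <- dplyr::mutate(target,
                          transcript_id = paste0(!!transcript_id, "_iso2"),
                          tpm = .data$tpm * (1 - .data$f), f = NULL)
    dplyr::bind_rows(rest, iso1, iso2)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
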