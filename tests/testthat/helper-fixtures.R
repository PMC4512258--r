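# Small in-code fixtures shared across test files.

# a tiny long-format posterior table: `spec` is a list of entries
#   list(tx, gene, sample, allele, draws)
make_posterior_tbl <- function(entries) {
  purrr::map(entries, function(e) {
    tibble::tibble(
      transcript_id = e[[1]], gene_id = e[[2]], sample_id = e[[3]],
      allele = e[[4]], draw_index = seq_along(e[[5]]), tpm = e[[5]]
    )
  }) |> dplyr::bind_rows()
}

# minimal braim_fit-shaped object from per-transcript wide values; `rows` is
# a tibble with transcript_id, gene_id, scale_sd and pp_/beta_ columns per
# effect (missing effects are filled with pp 0, beta 0)
make_fake_fit <- function(rows, effects = c("parental", "cross", "sex", "age")) {
  long <- purrr::pmap(rows, function(...) {
    r <- list(...)
    tibble::tibble(
      transcript_id = r$transcript_id,
      gene_id = r$gene_id %||% r$transcript_id,
      effect = effects,
      beta_mean = purrr::map_dbl(effects, \(e) r[[paste0("beta_", e)]] %||% 0),
      beta_sd = 0.1,
      pp = purrr::map_dbl(effects, \(e) r[[paste0("pp_", e)]] %||% 0),
      sigma2_mean = 1,
      scale_sd = r$scale_sd %||% 1,
      n = 48L
    )
  }) |> dplyr::bind_rows()
  structure(long, class = c("braim_fit", class(tibble::tibble())))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a quick small cohort for pipeline-level tests
small_cohort <- function(n_transcripts = 12, n_imprinted = 4, seed = 101,
                         n_per_block = 3, s_draws = 30, ...) {
  design <- braim::sim_design(n_per_block)
  specs <- braim::sim_transcript_specs(
    n_transcripts = n_transcripts, n_imprinted = n_imprinted,
    s_draws = s_draws, seed = seed, ...
  )
  sim <- braim::simulate_cohort(specs, design, seed = seed + 1)
  list(design = design, specs = specs, posteriors = sim$posteriors,
       truth = sim$truth)
}

fast_hyper <- function(n_iter = 2000L, burn_in = 500L, seed = 7L, ...) {
  braim::braim_hyper(n_iter = n_iter, burn_in = burn_in, seed = seed, ...)
}
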