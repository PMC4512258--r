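#' Apply the minimum-expression floor to a vector of posterior draws
#'
#' A transcript-sample whose posterior median TPM falls below the detection
#' floor `c` is treated as unexpressed in that sample: all of its draws are
#' replaced by the constant `c` (the minimal measurable expression level,
#' which also avoids taking the log of zero downstream). Draws whose median
#' is at or above the floor pass through unchanged — the rule acts on the
#' median, not draw by draw.
#'
#' @param draws Numeric vector of posterior TPM draws for one
#'   transcript-sample-allele.
#' @param c TPM floor (default 0.01).
#' @return The (possibly floored) draw vector.
#' @examples
#' floor_expression(c(0.001, 0.002), 0.01) # both replaced by 0.01
#' floor_expression(c(5, 6), 0.01)         # unchanged
#' @export
floor_expression <- function(draws, c = 0.01) {
  stopifnot(c > 0)
  if (stats::median(draws) < c) rep(c, length(draws)) else draws
}

#' Build the per-sample response and measurement-error variance
#'
#' For each sample the response is the posterior mean of a per-draw log
#' quantity, and the measurement-error variance is the posterior variance of
#' the same quantity (denominator S - 1). The per-draw quantity depends on
#' `mode`:
#' \describe{
#'   \item{diff}{`log(pat + c) - log(mat + c)` — the parental log-ratio, the
#'     default response for imprinting detection.}
#'   \item{paternal / maternal}{`log(allele + c)` — single-allele expression,
#'     used to attribute age regulation to one allele.}
#'   \item{overall}{`log(pat + mat + c)` — total expression.}
#' }
#'
#' @param pat,mat Numeric matrices of floored TPM draws, S rows (draws) by n
#'   columns (samples), aligned by draw index and sample.
#' @param mode One of `"diff"`, `"paternal"`, `"maternal"`, `"overall"`.
#' @param floor_c TPM floor constant added inside every log.
#' @return A list with numeric vectors `y_hat` and `err_var`, each length n.
#' @export
build_response <- function(pat, mat, mode = c("diff", "paternal", "maternal", "overall"),
                           floor_c = 0.01) {
  mode <- match.arg(mode)
  pat <- as.matrix(pat); mat <- as.matrix(mat)
  stopifnot(identical(dim(pat), dim(mat)))
  if (nrow(pat) < 2) {
    stop("at least S = 2 posterior draws are needed for the error variance",
         call. = FALSE)
  }
  ell <- switch(mode,
    diff     = log(pat + floor_c) - log(mat + floor_c),
    paternal = log(pat + floor_c),
    maternal = log(mat + floor_c),
    overall  = log(pat + mat + floor_c)
  )
  list(
    y_hat   = colMeans(ell),
    err_var = apply(ell, 2, stats::var)
  )
}

#' Scale a transcript's response to unit standard deviation
#'
#' Regression coefficients are sensitive to the scale of the response; to give
#' every transcript's effects a common interpretation the response is divided
#' by its across-sample standard deviation. Measurement-error variances are
#' divided by the across-sample *variance*, since variances transform with the
#' square of a scale factor. Scaled error variances are clamped below at 1e-8
#' so the measurement-error covariance stays invertible for floored
#' transcripts with exactly zero posterior spread.
#'
#' @param y_hat Length-n response vector (unscaled).
#' @param err_var Length-n vector of nonnegative measurement-error variances.
#' @return A list with `y_scaled`, `err_var_scaled` and `scale_sd`, or `NULL`
#'   (with a warning) when `sd(y_hat)` is zero and the transcript cannot be
#'   fitted.
#' @export
scale_response <- function(y_hat, err_var) {
  stopifnot(length(y_hat) == length(err_var), length(y_hat) >= 2,
            all(err_var >= 0))
  s <- stats::sd(y_hat)
  if (s == 0) {
    warning("response has zero standard deviation across samples; ",
            "transcript is un-fittable and will be skipped", call. = FALSE)
    return(NULL)
  }
  list(
    y_scaled = y_hat / s,
    err_var_scaled = pmax(err_var / s^2, 1e-8),
    scale_sd = s
  )
}

#' Build the +/-1 coded design matrix
#'
#' The first column is the intercept (all ones), whose coefficient is the
#' parental bias — the mean parental log-ratio across samples. Each remaining
#' factor is coded +1 for F1i, male and P8 and -1 for F1r, female and P60.
#' Per-age fits pass `factors = c("cross", "sex")` to drop the age column.
#'
#' @param design A sample-design tibble (see [read_design()]); row order
#'   defines the sample order of the response.
#' @param factors Character subset of `c("cross", "sex", "age")`.
#' @return A numeric matrix with column names
#'   `c("parental", factors)` and `nrow(design)` rows.
#' @export
build_design_matrix <- function(design, factors = c("cross", "sex", "age")) {
  stopifnot(nrow(design) > 0)
  factors <- match.arg(factors, c("cross", "sex", "age"), several.ok = TRUE)
  plus_level <- c(cross = "F1i", sex = "male", age = "P8")
  X <- matrix(1, nrow = nrow(design), ncol = 1 + length(factors),
              dimnames = list(design$sample_id, braim_effects(factors)))
  for (f in factors) {
    lev <- unique(design[[f]])
    if (length(lev) < 2) {
      stop(sprintf("factor `%s` has a single observed level (%s); drop it from `factors`",
                   f, lev), call. = FALSE)
    }
    X[, f] <- ifelse(design[[f]] == plus_level[[f]], 1, -1)
  }
  X
}

#' Build scaled response sets for every transcript in a cohort
#'
#' The tibble-level driver behind the model fit: floors every
#' transcript-sample-allele at the detection limit, computes the per-sample
#' response and measurement-error variance in the requested `mode`, and scales
#' each transcript's response to unit standard deviation. Transcripts whose
#' response is constant across samples (e.g. floored everywhere) are kept but
#' flagged `skipped`.
#'
#' @param posteriors A posterior-draw tibble (see [read_posterior_table()]).
#' @param design A sample-design tibble; its row order (after any `ages`
#'   subset) fixes the sample order of all responses.
#' @param mode Response mode, see [build_response()].
#' @param floor_c TPM floor.
#' @param ages Optional subset of `c("P8", "P60")` restricting the samples.
#' @param stringent_cutoff Optional log-expression cutoff: transcripts whose
#'   mean ln(posterior-median TPM) across samples and alleles falls below it
#'   are dropped (the conventional stringent choice is -1.6). `NULL` (default)
#'   disables the filter.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   list-columns `y_hat`, `err_var`, `y_scaled`, `err_var_scaled`, plus
#'   `scale_sd`, `n` and `skipped`. The ordered sample ids are attached as
#'   attribute `"sample_ids"`.
#' @export
build_response_set <- function(posteriors, design,
                               mode = c("diff", "paternal", "maternal", "overall"),
                               floor_c = 0.01, ages = NULL,
                               stringent_cutoff = NULL) {
  mode <- match.arg(mode)
  design <- tibble::as_tibble(design)
  if (!is.null(ages)) design <- dplyr::filter(design, .data$age %in% ages)
  if (nrow(design) < 2) stop("fewer than 2 samples after the age subset", call. = FALSE)
  tab <- posteriors |> dplyr::filter(.data$sample_id %in% design$sample_id)

  # floor per (transcript, sample, allele) on the posterior median
  tab <- tab |>
    dplyr::group_by(.data$transcript_id, .data$sample_id, .data$allele) |>
    dplyr::mutate(tpm = floor_expression(.data$tpm, floor_c)) |>
    dplyr::ungroup()

  if (!is.null(stringent_cutoff)) {
    keep <- tab |>
      dplyr::group_by(.data$transcript_id, .data$sample_id, .data$allele) |>
      dplyr::summarise(med = stats::median(.data$tpm), .groups = "drop") |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(mean_log = mean(log(.data$med)), .groups = "drop") |>
      dplyr::filter(.data$mean_log >= stringent_cutoff)
    tab <- dplyr::semi_join(tab, keep, by = "transcript_id")
  }

  wide <- tab |>
    tidyr::pivot_wider(
      id_cols = c("transcript_id", "gene_id", "sample_id", "draw_index"),
      names_from = "allele", values_from = "tpm"
    )
  ell <- switch(mode,
    diff     = log(wide$paternal + floor_c) - log(wide$maternal + floor_c),
    paternal = log(wide$paternal + floor_c),
    maternal = log(wide$maternal + floor_c),
    overall  = log(wide$paternal + wide$maternal + floor_c)
  )
  per_sample <- wide |>
    dplyr::mutate(ell = ell) |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$sample_id) |>
    dplyr::summarise(y_hat = mean(.data$ell), err_var = stats::var(.data$ell),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = design$sample_id)) |>
    dplyr::arrange(.data$transcript_id, .data$sample_id)

  out <- per_sample |>
    dplyr::group_by(.data$transcript_id, .data$gene_id) |>
    dplyr::summarise(y_hat = list(.data$y_hat), err_var = list(.data$err_var),
                     .groups = "drop")
  scaled <- purrr::map(seq_len(nrow(out)), function(i) {
    withCallingHandlers(
      scale_response(out$y_hat[[i]], out$err_var[[i]]),
      warning = function(w) {
        message("skipping ", out$transcript_id[i], ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  })
  out$y_scaled <- purrr::map(scaled, \(s) if (is.null(s)) NULL else s$y_scaled)
  out$err_var_scaled <- purrr::map(scaled, \(s) if (is.null(s)) NULL else s$err_var_scaled)
  out$scale_sd <- purrr::map_dbl(scaled, \(s) if (is.null(s)) NA_real_ else s$scale_sd)
  out$n <- lengths(out$y_hat)
  out$skipped <- purrr::map_lgl(scaled, is.null)
  attr(out, "sample_ids") <- design$sample_id
  attr(out, "mode") <- mode
  attr(out, "floor_c") <- floor_c
  out
}

#' Flag in which age groups each transcript is expressed
#'
#' A transcript counts as expressed in an age group when at least one sample
#' of that group has posterior median TPM at or above the floor. Transcripts
#' expressed exclusively in one age group are eligible for the single-age
#' imprinting call (see [call_imprinting()]).
#'
#' @inheritParams build_response_set
#' @return A tibble with `transcript_id`, `expressed_P8`, `expressed_P60`.
#' @export
expressed_by_age <- function(posteriors, design, floor_c = 0.01) {
  posteriors |>
    dplyr::inner_join(dplyr::select(design, "sample_id", "age"), by = "sample_id") |>
    dplyr::group_by(.data$transcript_id, .data$sample_id, .data$age) |>
    dplyr::summarise(med = stats::median(.data$tpm), .groups = "drop") |>
    dplyr::group_by(.data$transcript_id, .data$age) |>
    dplyr::summarise(expressed = any(.data$med >= floor_c), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "age", values_from = "expressed",
                       names_prefix = "expressed_", values_fill = FALSE)
}
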