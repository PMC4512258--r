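#' Recovery of simulated ground truth by the fitted calls
#'
#' Confusion summary of the imprinting calls against the simulation truth:
#' counts, sensitivity and specificity on the imprinted/not-imprinted label,
#' and the mean absolute error of the estimated versus true paternal
#' fraction among truly imprinted transcripts.
#'
#' @param calls A [call_imprinting()] tibble.
#' @param truth A truth tibble from [simulate_cohort()].
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `fraction_mae`.
#' @export
recovery_report <- function(calls, truth) {
  if (!all(calls$transcript_id %in% truth$transcript_id)) {
    stop("calls contain transcript ids absent from the truth table", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(calls, "transcript_id", "imprinted", "paternal_fraction"),
    dplyr::select(truth, "transcript_id", "is_imprinted", "true_paternal_fraction"),
    by = "transcript_id"
  )
  tp <- sum(joined$imprinted & joined$is_imprinted)
  fp <- sum(joined$imprinted & !joined$is_imprinted)
  tn <- sum(!joined$imprinted & !joined$is_imprinted)
  fn <- sum(!joined$imprinted & joined$is_imprinted)
  pos <- dplyr::filter(joined, .data$is_imprinted)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fraction_mae = if (nrow(pos) > 0) {
      mean(abs(pos$paternal_fraction - pos$true_paternal_fraction))
    } else NA_real_
  )
}

#' Bookkeeping summary of a validation campaign
#'
#' Given the headline counts of an imprinting survey — how many detected
#' genes were already known, how many novel candidates went to independent
#' validation and how many were confirmed, the size of the prior catalogue
#' of imprinted genes, and the clustering tallies — this computes the
#' derived percentages: validation precision, relative growth of the
#' catalogue, the clustered fraction of all imprinted genes, and the
#' isolated fraction of the confirmed novel genes.
#'
#' @param n_known Detected genes previously validated as imprinted.
#' @param n_novel_candidate Novel candidate genes sent to validation.
#' @param n_novel_confirmed Novel candidates confirmed by validation.
#' @param n_prior_catalog Imprinted genes known before the survey.
#' @param n_imprinted_total Total imprinted genes considered in the
#'   clustering tally.
#' @param n_clustered How many of those lie within 1 MB of another
#'   imprinted gene.
#' @param n_novel_isolated Confirmed novel genes isolated in the genome.
#' @return A one-row tibble of percentages: `precision_pct`,
#'   `catalog_increase_pct`, `clustered_pct`, `novel_isolated_pct`, plus
#'   `catalog_after` (the grown catalogue size).
#' @export
tally_validation <- function(n_known, n_novel_candidate, n_novel_confirmed,
                             n_prior_catalog, n_imprinted_total,
                             n_clustered, n_novel_isolated) {
  tibble::tibble(
    precision_pct = 100 * (n_known + n_novel_confirmed) /
      (n_known + n_novel_candidate),
    catalog_increase_pct = 100 * n_novel_confirmed / n_prior_catalog,
    catalog_after = n_prior_catalog + n_novel_confirmed,
    clustered_pct = 100 * n_clustered / n_imprinted_total,
    novel_isolated_pct = 100 * n_novel_isolated / n_novel_confirmed
  )
}
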