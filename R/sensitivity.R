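#' Perturbation grid for the one-at-a-time sensitivity analysis
#'
#' Each hyperparameter's empirical default is perturbed with four alternative
#' values: \eqn{\tau} both far below and above its default (0.005, 0.01, 1,
#' 2); \eqn{c} only around and above the approximate minimum usable value
#' (1.7, 3.4, 5.3125, 10.625); \eqn{\nu} upward only since it cannot fall
#' below 2 (5, 12.5, 25, 50); \eqn{\lambda} from informative to
#' uninformative (0.002, 0.004, 0.4, 0.8); and the prior inclusion
#' probability upward (0.2, 0.3, 0.4, 0.5).
#'
#' @param parameter One of `"tau"`, `"c_mult"`, `"nu"`, `"lam"`, `"prior_p"`.
#' @return Numeric vector of four perturbed values.
#' @export
perturbation_grid <- function(parameter = c("tau", "c_mult", "nu", "lam", "prior_p")) {
  parameter <- match.arg(parameter)
  switch(parameter,
    tau     = c(0.005, 0.01, 1, 2),
    c_mult  = c(1.7, 3.4, 5.3125, 10.625),
    nu      = c(5, 12.5, 25, 50),
    lam     = c(0.002, 0.004, 0.4, 0.8),
    prior_p = c(0.2, 0.3, 0.4, 0.5)
  )
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' AUC equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative; tied scores share average rank and count one
#' half. Being rank-based, the AUC is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param truth Binary (0/1 or logical) ground-truth labels; at least one
#'   positive and one negative.
#' @param scores Numeric scores, higher meaning more positive.
#' @return The AUC, in \[0, 1\].
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(truth) == length(scores))
  n1 <- sum(truth); n0 <- length(truth) - n1
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs at least one positive and one negative label", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-at-a-time hyperparameter sensitivity analysis
#'
#' Draws a transcript subsample once, fits the model with unperturbed
#' hyperparameters to define ground-truth positives (parental PP above the
#' calling cutoff), then refits the subsample for each parameter-value pair
#' with only that parameter changed and scores the perturbed parental PPs by
#' ROC/AUC against those labels. The same MCMC seed is reused across
#' perturbations so ranking differences reflect the hyperparameters, not
#' Monte-Carlo noise. A subsample with no positives (or no negatives) is
#' flagged not-evaluable rather than given a degenerate AUC.
#'
#' @param posteriors A posterior-draw tibble.
#' @param design A sample-design tibble.
#' @param hyper Unperturbed hyperparameters ([braim_hyper()]).
#' @param sample_fraction Fraction of transcripts to subsample (default 0.10).
#' @param parameters Which hyperparameters to perturb (default all five).
#' @param baseline_fit Optional precomputed unperturbed [braim_fit()] on the
#'   full `posteriors`; avoids refitting when available.
#' @param seed Seed for the transcript subsample (default `hyper$seed`).
#' @param engine Gibbs engine.
#' @return A tibble with one row per perturbation: `parameter`, `value`,
#'   `auc`, `n_transcripts`, `n_positive`, `evaluable`. The unperturbed
#'   self-comparison is included as `parameter = "none"`.
#' @export
run_sensitivity <- function(posteriors, design, hyper = braim_hyper(),
                            sample_fraction = 0.10,
                            parameters = c("tau", "c_mult", "nu", "lam", "prior_p"),
                            baseline_fit = NULL, seed = hyper$seed,
                            engine = "cpp") {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  ids <- unique(posteriors$transcript_id)
  n_sub <- max(2L, ceiling(length(ids) * sample_fraction))
  sub_ids <- withr::with_seed(seed, sample(ids, n_sub))
  sub <- dplyr::filter(posteriors, .data$transcript_id %in% sub_ids)
  rs_sub <- build_response_set(sub, design)

  base <- if (!is.null(baseline_fit)) {
    dplyr::filter(tibble::as_tibble(baseline_fit),
                  .data$transcript_id %in% sub_ids, .data$effect == "parental")
  } else {
    dplyr::filter(tibble::as_tibble(
      braim_fit(sub, design, hyper, engine = engine, response_set = rs_sub)
    ), .data$effect == "parental")
  }
  truth <- setNames(base$pp > hyper$pp_cutoff, base$transcript_id)
  n_pos <- sum(truth)
  evaluable <- n_pos > 0 && n_pos < length(truth)
  if (!evaluable) {
    warning("subsample has no positives or no negatives; AUCs not evaluable",
            call. = FALSE)
  }

  self_auc <- if (evaluable) roc_auc(truth, base$pp) else NA_real_
  rows <- list(tibble::tibble(
    parameter = "none", value = NA_real_, auc = self_auc,
    n_transcripts = length(truth), n_positive = n_pos, evaluable = evaluable
  ))
  for (par in parameters) {
    for (val in perturbation_grid(par)) {
      auc <- NA_real_
      if (evaluable) {
        h <- hyper
        h[[par]] <- val
        if (par == "nu") h$lam <- hyper$lam  # one-at-a-time: lam stays fixed
        pert <- dplyr::filter(tibble::as_tibble(
          braim_fit(sub, design, h, engine = engine, response_set = rs_sub)
        ), .data$effect == "parental")
        scores <- pert$pp[match(names(truth), pert$transcript_id)]
        auc <- roc_auc(truth, scores)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = par, value = val, auc = auc,
        n_transcripts = length(truth), n_positive = n_pos,
        evaluable = evaluable
      )
    }
  }
  dplyr::bind_rows(rows)
}
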