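#' Posterior probability of an effect from its inclusion-indicator draws
#'
#' The posterior probability (PP) of an effect is the arithmetic mean of the
#' retained 0/1 inclusion-indicator draws for that effect. An effect is
#' called significant when its PP exceeds the cutoff (0.95 by default
#' throughout the package).
#'
#' @param delta_draws Vector (or one-column matrix) of retained 0/1 draws.
#' @return The PP, a proportion in \[0, 1\].
#' @export
posterior_probability <- function(delta_draws) {
  delta_draws <- as.numeric(delta_draws)
  if (length(delta_draws) == 0) stop("no retained indicator draws", call. = FALSE)
  mean(delta_draws)
}

#' Parental expression fractions from the unscaled parental coefficient
#'
#' The parental coefficient on the unscaled response is the mean paternal -
#' maternal natural-log expression ratio across samples, so its exponential
#' is the ratio of the geometric-mean paternal to maternal expression.
#' Normalising the two geometric means to sum to one gives the logistic map
#' \deqn{f_{pat} = \frac{e^{\hat\beta}}{1 + e^{\hat\beta}}, \qquad
#'       f_{mat} = 1 - f_{pat}.}
#' A fraction of 0.5 is biallelic expression; 1.0 is exclusively paternal.
#'
#' @param beta_parental_unscaled The parental-effect posterior mean mapped
#'   back to the unscaled response (scaled-fit mean times `scale_sd`).
#' @return A named numeric vector `c(paternal, maternal)` summing to 1.
#' @examples
#' parental_fractions(log(4)) # 0.8 paternal, 0.2 maternal
#' @export
parental_fractions <- function(beta_parental_unscaled) {
  pat <- plogis(beta_parental_unscaled)
  c(paternal = pat, maternal = 1 - pat)
}

#' Preferred-allele bias from the parental fractions
#'
#' The parental bias of a transcript is the expression fraction of its
#' preferred (more highly expressed) allele: `max(paternal, maternal)`,
#' always in \[0.5, 1\].
#'
#' @param fractions Numeric vector of the two parental fractions.
#' @return The bias, a scalar in \[0.5, 1\].
#' @export
preferred_bias <- function(fractions) {
  max(fractions)
}

#' Call imprinting from combined and per-age fits
#'
#' A transcript is called imprinted when any of three rules fires:
#' \enumerate{
#'   \item its parental-effect PP exceeds the cutoff in the combined
#'     (both-ages) fit;
#'   \item it is expressed exclusively in one age group and its parental PP
#'     exceeds the cutoff in that group's fit;
#'   \item its age-effect PP exceeds the cutoff in the combined fit and its
#'     parental PP exceeds the cutoff in either single-age fit (a strong
#'     parental bias present at only one age can null out the combined
#'     parental PP).
#' }
#' The preferred allele comes from the sign of the parental coefficient
#' (positive = paternal, since the response is paternal - maternal), taken
#' from the fit that triggered the call.
#'
#' @param fit_combined A [braim_fit()] on all samples (may be `NULL` if a
#'   per-age fit is supplied).
#' @param fit_p8,fit_p60 Optional [braim_fit()] objects on the single-age
#'   subsets.
#' @param cutoff PP significance cutoff in (0, 1).
#' @param expressed Optional tibble from [expressed_by_age()]; required for
#'   rule 2. Transcripts absent from it are assumed expressed at both ages.
#' @return A tibble of class `"braim_calls"`, one row per transcript:
#'   `transcript_id`, `gene_id`, `imprinted`, `preferred_allele`,
#'   `paternal_fraction`, `maternal_fraction`, `bias`, `significant_effects`
#'   (list column), `source_fit`, `age_regulated`.
#' @export
call_imprinting <- function(fit_combined, fit_p8 = NULL, fit_p60 = NULL,
                            cutoff = 0.95, expressed = NULL) {
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)", call. = FALSE)
  if (is.null(fit_combined) && is.null(fit_p8) && is.null(fit_p60)) {
    stop("at least one fit must be supplied", call. = FALSE)
  }
  summ <- function(fit) if (is.null(fit)) NULL else fit_wide(fit)
  sc <- summ(fit_combined); s8 <- summ(fit_p8); s60 <- summ(fit_p60)

  ids <- dplyr::bind_rows(
    if (!is.null(sc)) sc[c("transcript_id", "gene_id")],
    if (!is.null(s8)) s8[c("transcript_id", "gene_id")],
    if (!is.null(s60)) s60[c("transcript_id", "gene_id")]
  ) |> dplyr::distinct()

  get <- function(s, id, col) {
    if (is.null(s)) return(NA_real_)
    i <- match(id, s$transcript_id)
    if (is.na(i) || !col %in% names(s)) NA_real_ else s[[col]][i]
  }
  rows <- purrr::pmap(ids, function(transcript_id, gene_id) {
    id <- transcript_id
    pp_par_c <- get(sc, id, "pp_parental")
    pp_age_c <- get(sc, id, "pp_age")
    pp_par_8 <- get(s8, id, "pp_parental")
    pp_par_60 <- get(s60, id, "pp_parental")
    ex8 <- TRUE; ex60 <- TRUE
    if (!is.null(expressed)) {
      i <- match(id, expressed$transcript_id)
      if (!is.na(i)) {
        ex8 <- expressed$expressed_P8[i]
        ex60 <- expressed$expressed_P60[i]
      }
    }
    rule1 <- isTRUE(pp_par_c > cutoff)
    rule2_p8 <- ex8 && !ex60 && isTRUE(pp_par_8 > cutoff)
    rule2_p60 <- ex60 && !ex8 && isTRUE(pp_par_60 > cutoff)
    rule3 <- isTRUE(pp_age_c > cutoff) &&
      (isTRUE(pp_par_8 > cutoff) || isTRUE(pp_par_60 > cutoff))
    imprinted <- rule1 || rule2_p8 || rule2_p60 || rule3

    source_fit <- if (rule1 || rule3 || (!rule2_p8 && !rule2_p60)) "combined"
      else if (rule2_p8) "P8_only" else "P60_only"
    # for rule-3 calls the parental sign comes from the significant age fit
    src <- if (rule1 || !imprinted) sc
      else if (rule2_p8) s8 else if (rule2_p60) s60
      else if (isTRUE(pp_par_8 > cutoff)) s8 else s60
    if (is.null(src)) src <- sc %||% s8 %||% s60
    beta_unscaled <- get(src, id, "beta_parental") * get(src, id, "scale_sd")
    if (is.na(beta_unscaled)) beta_unscaled <- 0
    fr <- parental_fractions(beta_unscaled)
    sig <- character()
    if (!is.null(sc)) {
      for (eff in c("parental", "cross", "sex", "age")) {
        v <- get(sc, id, paste0("pp_", eff))
        if (isTRUE(v > cutoff)) sig <- c(sig, eff)
      }
    }
    tibble::tibble(
      transcript_id = id, gene_id = gene_id, imprinted = imprinted,
      preferred_allele = if (!imprinted) "none"
        else if (beta_unscaled >= 0) "paternal" else "maternal",
      paternal_fraction = unname(fr["paternal"]),
      maternal_fraction = unname(fr["maternal"]),
      bias = preferred_bias(fr),
      significant_effects = list(sig),
      source_fit = if (imprinted) source_fit else "combined",
      age_regulated = isTRUE(pp_age_c > cutoff)
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("braim_calls", class(tibble::tibble())),
            cutoff = cutoff)
}

# one row per transcript with pp_<effect>, beta_<effect>, scale_sd columns
fit_wide <- function(fit) {
  tibble::as_tibble(fit) |>
    dplyr::select("transcript_id", "gene_id", "effect", "beta_mean", "pp",
                  "scale_sd") |>
    tidyr::pivot_wider(
      names_from = "effect", values_from = c("beta_mean", "pp"),
      names_glue = "{.value}_{effect}"
    ) |>
    dplyr::rename_with(\(x) sub("^beta_mean_", "beta_", x))
}

#' @describeIn call_imprinting Distribution of parental bias among imprinted
#'   transcripts.
#' @param object A `braim_calls` tibble.
#' @param ... Unused.
#' @method autoplot braim_calls
#' @export
autoplot.braim_calls <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$imprinted)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bias)) +
    ggplot2::geom_histogram(breaks = seq(0.5, 1, by = 0.025), fill = "grey30") +
    ggplot2::labs(x = "parental bias (preferred-allele fraction)",
                  y = "imprinted transcripts") +
    ggplot2::theme_minimal()
}
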