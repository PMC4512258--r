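#' Select the representative transcript of a gene
#'
#' A gene is represented by its isoform with the most significant parental
#' bias: maximal parental-effect PP, ties broken by larger absolute parental
#' coefficient, then lexicographically smallest transcript id. The same rule
#' selects between host and resident genes sharing a genomic location.
#'
#' @param fit_summary A tibble with one row per transcript and columns
#'   `transcript_id`, `pp` (parental PP) and `beta_mean` (parental
#'   coefficient), e.g. a filtered [tidy()] of a [braim_fit()].
#' @return The chosen `transcript_id`.
#' @export
select_representative <- function(fit_summary) {
  stopifnot(nrow(fit_summary) >= 1)
  ord <- order(-fit_summary$pp, -abs(fit_summary$beta_mean),
               fit_summary$transcript_id)
  fit_summary$transcript_id[ord[1]]
}

#' Assign imprinted genes to genomic clusters around strongly biased centers
#'
#' Scans each chromosome 5' to 3' and chains genes whose start lies within
#' `max_gap` of the previous gene's end into one cluster. Genes whose
#' preferred-allele bias reaches `center_threshold` (85:15 by default) are
#' candidate centers; physically consecutive candidates are grouped into a
#' single center interval. A cluster with several center groups is broken
#' into sub-clusters with boundaries halfway between adjacent center groups
#' (`max_gap` beyond the extreme groups); each member gene joins the
#' sub-cluster whose downstream boundary is the first at or beyond its start
#' site. Genes whose start lies more than `max_gap` from their center are
#' dropped. Input coordinates must be strand-normalised (antisense genes'
#' start/end swapped to sense orientation, so `start < end` always);
#' [read_gene_bed()] plus [normalize_strand()] produce this.
#'
#' @param genes Tibble with columns `gene_id`, `chromosome`, `start`, `end`
#'   and `bias` (preferred-allele fraction in \[0.5, 1\]).
#' @param center_threshold Minimum bias of a center gene (default 0.85).
#' @param max_gap Chaining distance and removal radius in bp (default 1 MB).
#' @return A tibble of class `"braim_clusters"`: `gene_id`, `chromosome`,
#'   `start`, `end`, `bias`, `cluster_id`, `is_center`, `center_start`,
#'   `center_end`, `distance_bp` (start site to nearest center edge, 0
#'   inside; `NA` in clusters without a center).
#' @export
assign_clusters <- function(genes, center_threshold = 0.85, max_gap = 1e6) {
  genes <- tibble::as_tibble(genes) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$end)
  stopifnot(all(genes$start < genes$end), all(genes$bias >= 0.5 - 1e-9))

  # chain into clusters per chromosome
  genes <- genes |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(
      new_cluster = c(TRUE, .data$start[-1] - .data$end[-dplyr::n()] > max_gap),
      cluster_idx = cumsum(.data$new_cluster)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster_id = paste0(.data$chromosome, "_c", .data$cluster_idx)) |>
    dplyr::select(-"new_cluster", -"cluster_idx")

  per_cluster <- split(genes, genes$cluster_id)
  out <- purrr::map(per_cluster, function(cl) {
    cl <- dplyr::arrange(cl, .data$start, .data$end)
    cand <- cl$bias >= center_threshold
    if (!any(cand)) {
      cl$is_center <- FALSE
      cl$center_start <- NA_real_; cl$center_end <- NA_real_
      cl$distance_bp <- NA_real_
      cl$subcluster <- 1L
      return(cl)
    }
    # group physically consecutive candidate centers
    run <- rle(cand)
    run_id <- rep(seq_along(run$lengths), run$lengths)
    center_groups <- unique(run_id[cand])
    centers <- purrr::map(center_groups, function(g) {
      idx <- which(run_id == g)
      c(start = min(cl$start[idx]), end = max(cl$end[idx]))
    })
    k <- length(centers)
    # sub-cluster right boundaries: midpoints between adjacent center groups,
    # max_gap beyond the last one
    bounds <- numeric(k)
    for (i in seq_len(k)) {
      bounds[i] <- if (i < k) {
        (centers[[i]]["end"] + centers[[i + 1]]["start"]) / 2
      } else {
        centers[[i]]["end"] + max_gap
      }
    }
    sub <- vapply(cl$start, function(s) {
      w <- which(bounds >= s)
      if (length(w) == 0) k else w[1]
    }, integer(1))
    # center genes always belong to their own sub-cluster
    for (i in seq_len(k)) sub[run_id == center_groups[i]] <- i
    cl$subcluster <- sub
    cl$is_center <- cand
    cl$center_start <- vapply(sub, \(i) centers[[i]][["start"]], numeric(1))
    cl$center_end <- vapply(sub, \(i) centers[[i]][["end"]], numeric(1))
    cl$distance_bp <- pmax(pmax(cl$center_start - cl$start,
                                cl$start - cl$center_end), 0)
    cl
  }) |> dplyr::bind_rows()

  out <- out |>
    dplyr::mutate(cluster_id = dplyr::if_else(
      is.na(.data$distance_bp), .data$cluster_id,
      paste0(.data$cluster_id, "s", .data$subcluster)
    )) |>
    dplyr::filter(is.na(.data$distance_bp) | .data$distance_bp <= max_gap) |>
    dplyr::select(-"subcluster") |>
    dplyr::arrange(.data$chromosome, .data$start)
  structure(out, class = c("braim_clusters", class(tibble::tibble())))
}

#' Normalise gene coordinates to sense orientation
#'
#' Antisense genes' start and end sites are represented by their end and
#' start sites on the sense strand, i.e. intervals are reported with
#' `start < end` regardless of strand. BED input already satisfies this;
#' the function exists to make the convention explicit and to repair tables
#' where antisense coordinates were swapped.
#'
#' @param genes Tibble with `start`, `end` and optionally `strand`.
#' @return The tibble with `start <= end` everywhere.
#' @export
normalize_strand <- function(genes) {
  sw <- genes$start > genes$end
  if (any(sw)) {
    tmp <- genes$start[sw]
    genes$start[sw] <- genes$end[sw]
    genes$end[sw] <- tmp
  }
  genes
}

#' Regress parental bias on distance from the cluster center
#'
#' Ordinary least squares of the preferred-allele bias of non-center cluster
#' members on their distance (bp) from the cluster center, pooled across
#' clusters with a single shared slope. A negative, significant slope
#' supports a decay of parental bias away from imprinted cluster centers.
#'
#' @param assignments A [assign_clusters()] result.
#' @return A one-row tibble: `slope`, `intercept`, `slope_p_value`,
#'   `n_genes`.
#' @export
decay_regression <- function(assignments) {
  dat <- assignments |>
    dplyr::filter(!.data$is_center, is.finite(.data$distance_bp))
  if (nrow(dat) < 3) {
    stop("decay regression needs at least 3 non-center genes with finite distances",
         call. = FALSE)
  }
  fit <- stats::lm(bias ~ distance_bp, data = dat)
  co <- summary(fit)$coefficients
  tibble::tibble(
    slope = co["distance_bp", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    slope_p_value = co["distance_bp", "Pr(>|t|)"],
    n_genes = nrow(dat)
  )
}

#' @describeIn assign_clusters Bias versus distance-from-center scatter with
#'   the pooled decay regression line.
#' @param object A `braim_clusters` tibble.
#' @param ... Unused.
#' @method autoplot braim_clusters
#' @export
autoplot.braim_clusters <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !.data$is_center,
                       is.finite(.data$distance_bp))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance_bp, y = .data$bias)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "magenta") +
    ggplot2::labs(x = "distance from cluster center (bp)",
                  y = "parental bias") +
    ggplot2::theme_minimal()
}
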