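#' Mean posterior correlation between two transcripts of one gene and allele
#'
#' Highly similar isoforms are often not distinguishable by the read data;
#' the reads are then split ambiguously between them and their posterior
#' expression draws become strongly anti-correlated within each sample. For
#' a pair of draw matrices (S draws by n samples, aligned by draw index) this
#' computes the Pearson correlation over the S paired draws in each sample
#' and averages across samples. A sample in which either transcript has zero
#' draw variance (e.g. both floored) contributes r = 0.
#'
#' @param a,b Numeric S-by-n matrices of posterior TPM draws.
#' @return The mean per-sample Pearson correlation.
#' @export
posterior_correlation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) {
    stop("draw matrices must share dimensions (same S, same samples)", call. = FALSE)
  }
  r <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  mean(r)
}

#' Combine lowly identifiable transcripts by posterior anti-correlation
#'
#' Within each gene, any pair of units (original transcripts or already
#' combined ones) whose mean posterior correlation is below `cutoff` on
#' *both* alleles is a merge candidate; the pair with the most negative
#' correlation (averaged over the two alleles) is merged first, its draws
#' summed elementwise per sample and allele, correlations are recomputed, and
#' the process repeats until no pair qualifies. Requiring the cutoff on both
#' alleles keeps the combined units identical between alleles, so they remain
#' testable for parental bias. Summing is the natural arithmetic: under
#' read-assignment ambiguity the summed abundance is the well-identified
#' quantity, and the sum of anti-correlated draws has smaller posterior
#' spread than either member.
#'
#' @param posteriors A posterior-draw tibble (see [read_posterior_table()]).
#' @param cutoff Mean-correlation merge threshold (default -0.25).
#' @return A list with `posteriors` (the table with merged units, combined
#'   ids being the sorted member ids joined by `"+"`) and `map` (tibble
#'   `original_id` -> `combined_id`, identity rows included).
#' @export
combine_transcripts <- function(posteriors, cutoff = -0.25) {
  posteriors <- tibble::as_tibble(posteriors)
  samples <- sort(unique(posteriors$sample_id))
  genes <- split(posteriors, posteriors$gene_id)
  out <- vector("list", length(genes))
  maps <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    # unit draw arrays: list[transcript] -> list(paternal = SxN, maternal = SxN)
    units <- purrr::map(split(g, g$transcript_id), function(tg) {
      purrr::map(c(paternal = "paternal", maternal = "maternal"), function(al) {
        sub <- tg[tg$allele == al, ]
        sub <- sub[order(match(sub$sample_id, samples), sub$draw_index), ]
        matrix(sub$tpm, ncol = length(unique(sub$sample_id)))
      })
    })
    members <- purrr::map(names(units), identity)
    names(members) <- names(units)
    repeat {
      ids <- names(units)
      if (length(ids) < 2) break
      best <- NULL; best_score <- Inf
      for (i in seq_len(length(ids) - 1)) {
        for (j in seq(i + 1, length(ids))) {
          rp <- posterior_correlation(units[[i]]$paternal, units[[j]]$paternal)
          rm <- posterior_correlation(units[[i]]$maternal, units[[j]]$maternal)
          if (rp < cutoff && rm < cutoff) {
            score <- (rp + rm) / 2
            if (score < best_score) {
              best_score <- score
              best <- c(i, j)
            }
          }
        }
      }
      if (is.null(best)) break
      i <- best[1]; j <- best[2]
      merged <- list(
        paternal = units[[i]]$paternal + units[[j]]$paternal,
        maternal = units[[i]]$maternal + units[[j]]$maternal
      )
      new_members <- sort(c(members[[ids[i]]], members[[ids[j]]]))
      new_id <- paste(new_members, collapse = "+")
      units[[ids[i]]] <- NULL
      units[[ids[j]]] <- NULL
      units[[new_id]] <- merged
      members[[ids[i]]] <- NULL
      members[[ids[j]]] <- NULL
      members[[new_id]] <- new_members
    }
    s_draws <- nrow(units[[1]]$paternal)
    out[[gi]] <- purrr::imap(units, function(u, id) {
      purrr::imap(u, function(m, al) {
        tibble::tibble(
          transcript_id = id, gene_id = g$gene_id[1],
          sample_id = rep(samples, each = s_draws), allele = al,
          draw_index = rep(seq_len(s_draws), times = length(samples)),
          tpm = as.vector(m)
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    maps[[gi]] <- purrr::imap(members, \(m, id) tibble::tibble(
      original_id = m, combined_id = id
    )) |> dplyr::bind_rows()
  }
  list(posteriors = dplyr::bind_rows(out), map = dplyr::bind_rows(maps))
}
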