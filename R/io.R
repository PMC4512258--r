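#' Read a long-format table of allele-specific posterior expression draws
#'
#' The on-disk format is a tidy TSV with one row per posterior draw:
#' columns `transcript_id`, `gene_id`, `sample_id`, `allele`
#' (`"paternal"`/`"maternal"`), `draw_index` (1..S) and `tpm` (expression in
#' TPM units). Every (transcript, sample) pair must carry both alleles with
#' the same number of draws S >= 2, and all pairs in a file share one S.
#'
#' @param path Path to the TSV file.
#' @return A tibble of the validated draws (the same long layout, with
#'   `allele` as character), ready for [build_response_set()].
#' @export
read_posterior_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_posteriors(tab)
}

#' Validate an in-memory posterior-draw table
#'
#' Enforces the invariants of the posterior-draw layout: required columns,
#' nonnegative TPM, both alleles present for every (transcript, sample) pair,
#' and a common draw count S >= 2. Violations are errors naming the offending
#' transcript/sample, never silently repaired.
#'
#' @param tab A data frame in the long posterior-draw layout.
#' @return The table as a tibble, invisibly validated.
#' @export
validate_posteriors <- function(tab) {
  need <- c("transcript_id", "gene_id", "sample_id", "allele", "draw_index", "tpm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("posterior table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  bad_allele <- setdiff(unique(tab$allele), c("paternal", "maternal"))
  if (length(bad_allele) > 0) {
    stop("unknown allele level(s): ", paste(bad_allele, collapse = ", "), call. = FALSE)
  }
  if (any(tab$tpm < 0)) {
    off <- tab[tab$tpm < 0, ][1, ]
    stop(sprintf("negative TPM for transcript %s, sample %s",
                 off$transcript_id, off$sample_id), call. = FALSE)
  }
  counts <- tab |>
    dplyr::count(.data$transcript_id, .data$sample_id, .data$allele, name = "S")
  wide <- counts |>
    tidyr::pivot_wider(names_from = "allele", values_from = "S")
  if (!"maternal" %in% names(wide)) wide$maternal <- NA_integer_
  if (!"paternal" %in% names(wide)) wide$paternal <- NA_integer_
  orphan <- wide[is.na(wide$maternal) | is.na(wide$paternal), ]
  if (nrow(orphan) > 0) {
    side <- if (is.na(orphan$maternal[1])) "maternal" else "paternal"
    stop(sprintf("missing %s allele for transcript %s, sample %s",
                 side, orphan$transcript_id[1], orphan$sample_id[1]), call. = FALSE)
  }
  s_all <- unique(c(wide$paternal, wide$maternal))
  if (length(s_all) != 1) {
    off <- wide[wide$paternal != s_all[1] | wide$maternal != s_all[1], ][1, ]
    stop(sprintf("inconsistent draw count S for transcript %s, sample %s",
                 off$transcript_id, off$sample_id), call. = FALSE)
  }
  if (s_all < 2) stop("at least S = 2 posterior draws per allele are required", call. = FALSE)
  tab
}

#' Read a sample-design table
#'
#' A TSV with columns `sample_id`, `cross` (`F1i`/`F1r`), `sex`
#' (`male`/`female`) and `age` (`P8`/`P60`). F1i and F1r are the two
#' reciprocal-cross directions, which disentangle parent-of-origin from
#' strain-of-origin effects.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the validated design; empty files yield an empty
#'   tibble with a warning.
#' @export
read_design <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) {
    warning("design file ", path, " has no rows", call. = FALSE)
    return(tibble::tibble(sample_id = character(), cross = character(),
                          sex = character(), age = character()))
  }
  validate_design(tab)
}

#' Validate an in-memory sample-design table
#' @param tab A data frame with columns `sample_id`, `cross`, `sex`, `age`.
#' @return The design as a tibble.
#' @export
validate_design <- function(tab) {
  need <- c("sample_id", "cross", "sex", "age")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("design is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  levels_ok <- list(cross = c("F1i", "F1r"), sex = c("male", "female"),
                    age = c("P8", "P60"))
  for (col in names(levels_ok)) {
    bad <- setdiff(unique(tab[[col]]), levels_ok[[col]])
    if (length(bad) > 0) {
      stop(sprintf("unknown %s level(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  tab
}

#' Read gene coordinates from a BED file
#'
#' Six-column BED (`chrom`, `start`, `end`, `gene_id`, `score`, `strand`)
#' with 0-based half-open coordinates. The `score` column is ignored.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("chromosome", "start", "end", "gene_id", "score", "strand"),
    show_col_types = FALSE, progress = FALSE
  )
  if (any(tab$start >= tab$end)) {
    off <- tab[tab$start >= tab$end, ][1, ]
    stop(sprintf("gene %s has start >= end", off$gene_id), call. = FALSE)
  }
  bad <- setdiff(unique(tab$strand), c("+", "-"))
  if (length(bad) > 0) stop("unknown strand value(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  dplyr::select(tab, "gene_id", "chromosome", "start", "end", "strand")
}

#' Write per-transcript results to a TSV
#'
#' One row per transcript, combining the gene calls with the per-effect
#' posterior summaries of the fit: posterior mean and sd of each coefficient,
#' each effect's posterior probability, the parental expression fractions,
#' and the imprinted / age-regulated flags. Floating-point columns are
#' written with six decimals.
#'
#' @param calls A gene-call tibble from [call_imprinting()].
#' @param fit The fit the calls came from (a [braim_fit()] result).
#' @param path Output path.
#' @return The written wide tibble, invisibly.
#' @export
write_results <- function(calls, fit, path) {
  wide <- tidy(fit) |>
    dplyr::select("transcript_id", "effect", "beta_mean", "beta_sd", "pp") |>
    tidyr::pivot_wider(
      names_from = "effect",
      values_from = c("beta_mean", "beta_sd", "pp"),
      names_glue = "{effect}_{.value}"
    )
  out <- calls |>
    dplyr::left_join(wide, by = "transcript_id") |>
    dplyr::mutate(
      significant_effects = purrr::map_chr(.data$significant_effects,
                                           paste, collapse = ",")
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), \(x) round(x, 6)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Read back a results TSV written by [write_results()]
#' @param path Path to the results TSV.
#' @return A tibble; `significant_effects` is re-split into a list column.
#' @export
read_results <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) > 0 && "significant_effects" %in% names(tab)) {
    tab$significant_effects <- purrr::map(
      tab$significant_effects,
      \(x) if (is.na(x) || x == "") character() else strsplit(x, ",")[[1]]
    )
  }
  tab
}

#' Read a YAML run configuration
#'
#' The configuration mirrors [braim_hyper()] (any subset of its arguments
#' under a `hyper:` block) plus optional file paths (`posteriors`, `design`,
#' `out`) and run options (`mode`, `ages`). Command-line flags override
#' configuration values.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `hyper` (a `braim_hyper`) and `options`
#'   (everything else).
#' @export
read_braim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  hyper_args <- cfg$hyper %||% list()
  hyper <- do.call(braim_hyper, hyper_args)
  list(hyper = hyper, options = cfg[setdiff(names(cfg), "hyper")])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
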