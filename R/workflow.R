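#' Run the full imprinting-detection workflow
#'
#' Fits the model three times — to all samples (cross, sex and age effects),
#' and to the P8 and P60 subsets independently (cross and sex effects) —
#' applies the combined/per-age imprinting calling rules, and optionally
#' refits with single-allele responses to attribute significant age
#' regulation to the preferred or non-preferred parental allele (an allele
#' is age-regulated when its single-allele fit has age PP above the cutoff).
#'
#' @param posteriors A posterior-draw tibble.
#' @param design A sample-design tibble covering both ages.
#' @param hyper A [braim_hyper()] object.
#' @param floor_c TPM floor.
#' @param allele_modes Also fit `mode = "paternal"` and `"maternal"` and
#'   classify age regulation by allele (default FALSE; doubles the fitting
#'   cost).
#' @param engine Gibbs engine.
#' @return A list of class `"braim_workflow"`: `calls` (a
#'   [call_imprinting()] tibble, with an `age_regulation_class` column when
#'   `allele_modes` is on), `fit_combined`, `fit_p8`, `fit_p60`, `expressed`,
#'   and `manifest` (seed, hyperparameters, per-stage timings).
#' @export
run_fit_workflow <- function(posteriors, design, hyper = braim_hyper(),
                             floor_c = 0.01, allele_modes = FALSE,
                             engine = "cpp") {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("workflow stage `%s` failed: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("stage %-12s %6.1f s", what, proc.time()[["elapsed"]] - s))
    out
  }
  expressed <- stage("expression", expressed_by_age(posteriors, design, floor_c))
  fit_combined <- stage("combined",
    braim_fit(posteriors, design, hyper, floor_c = floor_c, engine = engine))
  fit_p8 <- stage("P8",
    braim_fit(posteriors, design, hyper, ages = "P8", floor_c = floor_c,
              engine = engine))
  fit_p60 <- stage("P60",
    braim_fit(posteriors, design, hyper, ages = "P60", floor_c = floor_c,
              engine = engine))
  calls <- stage("calling",
    call_imprinting(fit_combined, fit_p8, fit_p60,
                    cutoff = hyper$pp_cutoff, expressed = expressed))

  fits_allele <- NULL
  if (allele_modes) {
    fit_pat <- stage("paternal",
      braim_fit(posteriors, design, hyper, mode = "paternal",
                floor_c = floor_c, engine = engine))
    fit_mat <- stage("maternal",
      braim_fit(posteriors, design, hyper, mode = "maternal",
                floor_c = floor_c, engine = engine))
    fits_allele <- list(paternal = fit_pat, maternal = fit_mat)
    age_pp <- function(fit) {
      tibble::as_tibble(fit) |>
        dplyr::filter(.data$effect == "age") |>
        dplyr::select("transcript_id", "pp")
    }
    pat_age <- age_pp(fit_pat); mat_age <- age_pp(fit_mat)
    calls <- calls |>
      dplyr::left_join(dplyr::rename(pat_age, pp_age_paternal = "pp"),
                       by = "transcript_id") |>
      dplyr::left_join(dplyr::rename(mat_age, pp_age_maternal = "pp"),
                       by = "transcript_id") |>
      dplyr::mutate(
        age_regulation_class = purrr::pmap_chr(
          list(.data$preferred_allele, .data$pp_age_paternal,
               .data$pp_age_maternal),
          classify_age_regulation, cutoff = hyper$pp_cutoff
        )
      )
    class(calls) <- c("braim_calls", class(tibble::tibble()))
  }
  manifest <- list(
    seed = hyper$seed,
    hyper = unclass(hyper),
    n_transcripts = dplyr::n_distinct(posteriors$transcript_id),
    n_samples = nrow(design),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  structure(
    list(calls = calls, fit_combined = fit_combined, fit_p8 = fit_p8,
         fit_p60 = fit_p60, fits_allele = fits_allele,
         expressed = expressed, manifest = manifest),
    class = "braim_workflow"
  )
}

# which allele(s) change with age, relative to the preferred allele
classify_age_regulation <- function(preferred_allele, pp_pat, pp_mat, cutoff) {
  pat <- isTRUE(pp_pat > cutoff)
  mat <- isTRUE(pp_mat > cutoff)
  if (!pat && !mat) return("none")
  if (pat && mat) return("both_alleles")
  changed <- if (pat) "paternal" else "maternal"
  if (preferred_allele == "none") return("single_allele")
  if (changed == preferred_allele) "preferred_allele" else "non_preferred_allele"
}

#' @export
print.braim_workflow <- function(x, ...) {
  cat("<braim_workflow>\n")
  cat(sprintf("  %d transcripts, %d samples, %.1f s\n",
              x$manifest$n_transcripts, x$manifest$n_samples,
              x$manifest$elapsed_s))
  cat(sprintf("  imprinted calls: %d\n", sum(x$calls$imprinted)))
  invisible(x)
}

#' Write a JSON run manifest alongside a results file
#' @param workflow A [run_fit_workflow()] result.
#' @param path Output path for the manifest (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(workflow, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(manifest_json(workflow$manifest), tmp)
  file.rename(tmp, path)
  invisible(path)
}

# minimal JSON writer for the flat manifest (no added dependency)
manifest_json <- function(x, indent = "") {
  enc <- function(v) {
    if (is.list(v)) return(manifest_json(v, paste0(indent, "  ")))
    if (is.character(v)) {
      q <- paste0('"', v, '"')
      return(if (length(v) == 1) q else paste0("[", paste(q, collapse = ", "), "]"))
    }
    if (length(v) == 1) format(v, digits = 15) else
      paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
  }
  body <- purrr::imap_chr(x, \(v, k) sprintf('%s  "%s": %s', indent, k, enc(v)))
  paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}")
}
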