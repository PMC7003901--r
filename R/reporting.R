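#' Side-by-side comparison of two model fits
#'
#' Aligns the ratio-scale effect summaries of two fits (typically shared
#' model hazard ratios vs simple-model odds ratios) on the same
#' (treatment, outcome) grid, optionally adds the true effects of a
#' simulation scenario, and flags cells whose 95% credible intervals do not
#' overlap. Intervals are treated as closed: touching endpoints count as
#' overlapping.
#'
#' @param fit_a,fit_b two [fit_nma()] results (or their `effects$table`s)
#'   covering the same grid.
#' @param labels length-2 character: column prefixes for the two fits.
#' @param truth optional [scenario_spec()] whose `true_effects` supply a
#'   `true_ratio` column.
#' @return data.frame, one row per (treatment, outcome), with each fit's
#'   ratio mean and 95% CrI and a logical `disjoint` flag; also the data
#'   behind a forest-style plot.
#' @export
report_comparison <- function(fit_a, fit_b, labels = c("a", "b"),
                              truth = NULL) {
  tab <- function(f) if (inherits(f, "nma_fit")) f$effects$table else f
  a <- tab(fit_a)
  b <- tab(fit_b)
  key <- function(x) paste(x$treatment, x$outcome, sep = "\r")
  if (!identical(sort(key(a)), sort(key(b))))
    stop("fits do not cover the same (treatment, outcome) grid")
  b <- b[match(key(a), key(b)), ]
  out <- data.frame(treatment = a$treatment, outcome = a$outcome,
                    stringsAsFactors = FALSE)
  out[[paste0(labels[1L], "_ratio")]] <- a$hr_mean
  out[[paste0(labels[1L], "_lower")]] <- a$hr_q2.5
  out[[paste0(labels[1L], "_upper")]] <- a$hr_q97.5
  out[[paste0(labels[2L], "_ratio")]] <- b$hr_mean
  out[[paste0(labels[2L], "_lower")]] <- b$hr_q2.5
  out[[paste0(labels[2L], "_upper")]] <- b$hr_q97.5
  out$disjoint <- a$hr_q2.5 > b$hr_q97.5 | b$hr_q2.5 > a$hr_q97.5
  if (!is.null(truth)) {
    h <- truth$true_effects
    tt <- match(out$treatment, unique(out$treatment)) + 1L
    mm <- match(out$outcome, unique(out$outcome))
    out$true_ratio <- exp(h[cbind(tt, mm)])
  }
  out
}

#' Provenance manifest for a run
#'
#' Serializes the configuration, seeds and package version of a run into a
#' canonical JSON record so any reported number can be traced to, and
#' reproduced from, its manifest. Identical inputs give byte-identical
#' manifests.
#'
#' @param config named list describing the run (model, priors, scenario...).
#' @param seeds integer vector of every seed the run consumed.
#' @param versions named list or character vector of relevant versions;
#'   defaults to this package's version and the R version.
#' @param path optional file to write the manifest to.
#' @return The manifest JSON as a single string (invisibly if written).
#' @export
run_manifest <- function(config, seeds, versions = NULL, path = NULL) {
  if (is.null(seeds) || length(seeds) == 0L || anyNA(seeds))
    stop("a seed is required in the manifest")
  if (is.null(versions))
    versions <- list(
      sharednma = as.character(utils::packageVersion("sharednma")),
      R = paste(R.version$major, R.version$minor, sep = "."))
  manifest <- list(config = config, seeds = as.integer(seeds),
                   versions = versions)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
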