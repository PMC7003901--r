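#' Arm-level record of a trial arm
#'
#' Bundles the aggregate summaries for one arm of one trial: treatment code,
#' number randomized, exposure (person-years at risk), mean follow-up, and the
#' per-outcome event counts. Exactly how the counts are to be interpreted
#' (first events only, patients with at least one event, or total events)
#' is a property of the *study*, carried by its data format label.
#'
#' Either `person_years` or `mean_followup` may be omitted; the missing one is
#' derived from the other via \eqn{\bar T = E / n}. When both are supplied they
#' must agree to relative tolerance 1e-6.
#'
#' @param treatment integer treatment code (1 = network reference).
#' @param n number of patients randomized to the arm (> 0).
#' @param person_years total person-years at risk \eqn{E}, shared across
#'   outcomes. Optional if `mean_followup` is given.
#' @param mean_followup mean per-patient follow-up \eqn{\bar T} in years.
#'   Optional if `person_years` is given.
#' @param counts numeric vector of event counts indexed by outcome; entries
#'   may be `NA` for outcomes the study does not report.
#' @return An object of class `"nma_arm"`.
#' @export
arm_record <- function(treatment, n, person_years = NULL, mean_followup = NULL,
                       counts) {
  treatment <- as.integer(treatment)
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n_randomized must be a positive integer")
  if (is.na(treatment) || treatment < 1L) stop("treatment code must be >= 1")
  has_e <- !is.null(person_years) && !is.na(person_years)
  has_t <- !is.null(mean_followup) && !is.na(mean_followup)
  if (!has_e && !has_t)
    stop("incomplete record: one of person_years or mean_followup is required")
  if (has_e && person_years < 0) stop("person_years must be nonnegative")
  if (has_t && mean_followup < 0) stop("mean_followup must be nonnegative")
  if (has_e && has_t) {
    implied <- person_years / n
    if (abs(implied - mean_followup) > 1e-6 * max(1, abs(mean_followup)))
      stop(sprintf(
        "inconsistent exposure: person_years/n = %.8g but mean_followup = %.8g",
        implied, mean_followup))
  }
  if (!has_e) person_years <- n * mean_followup
  if (!has_t) mean_followup <- person_years / n
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("event counts must be nonnegative")
  if (any(counts != floor(counts), na.rm = TRUE))
    stop("event counts must be integers")
  structure(
    list(treatment = treatment, n = n, person_years = person_years,
         mean_followup = mean_followup, counts = counts),
    class = "nma_arm")
}

#' Person-years at risk for an arm
#'
#' Returns the exposure \eqn{E} for an arm, deriving \eqn{E = n \bar T} if only
#' mean follow-up was recorded. Exposure is outcome-independent.
#'
#' @param arm an [arm_record()].
#' @return Person-years at risk (numeric scalar).
#' @export
exposure <- function(arm) {
  if (!is.null(arm$person_years) && !is.na(arm$person_years))
    return(arm$person_years)
  if (!is.null(arm$mean_followup) && !is.na(arm$mean_followup))
    return(arm$n * arm$mean_followup)
  stop("incomplete record: neither person_years nor mean_followup present")
}

#' Study-level record
#'
#' A study is at least two ordered arms plus a data format label
#' \eqn{j \in \{1,2,3\}} describing how its event counts summarize the
#' underlying event processes:
#' \describe{
#'   \item{format 1}{counts are each patient's *first* event only (competing
#'     risks; patients are censored at their first event), so the counts over
#'     outcomes sum to at most `n` per arm;}
#'   \item{format 2}{counts are patients with at least one event of each
#'     outcome (a patient can appear under several outcomes);}
#'   \item{format 3}{counts are total events including within-patient repeats.}
#' }
#' All arms must report the same outcome set: outcome missingness is a
#' study-level property. Arms are kept in the order given; the first arm's
#' treatment acts as the trial's baseline in the network model.
#'
#' @param study_id identifier (coerced to character).
#' @param data_format integer 1, 2 or 3.
#' @param arms list of [arm_record()]s, trial baseline first.
#' @return An object of class `"nma_study"`.
#' @export
study_record <- function(study_id, data_format, arms) {
  data_format <- as.integer(data_format)
  if (!data_format %in% 1:3)
    stop(sprintf("study %s: data_format must be 1, 2 or 3", study_id))
  if (length(arms) < 2L)
    stop(sprintf("study %s: at least 2 arms required", study_id))
  rep_out <- lapply(arms, function(a) which(!is.na(a$counts)))
  for (k in seq_along(arms)[-1L]) {
    if (!identical(rep_out[[k]], rep_out[[1L]]))
      stop(sprintf("study %s arm %d: arms report different outcome sets",
                   study_id, k))
  }
  if (length(rep_out[[1L]]) == 0L)
    stop(sprintf("study %s: no reported outcomes", study_id))
  if (data_format == 1L) {
    for (k in seq_along(arms)) {
      tot <- sum(arms[[k]]$counts, na.rm = TRUE)
      if (tot > arms[[k]]$n)
        stop(sprintf(
          "study %s arm %d: first-event counts sum to %d > n = %d",
          study_id, k, as.integer(tot), arms[[k]]$n))
    }
  }
  structure(
    list(study_id = as.character(study_id), data_format = data_format,
         arms = arms, reported_outcomes = rep_out[[1L]]),
    class = "nma_study")
}

#' Multi-outcome, multi-format NMA evidence base
#'
#' Collects the study records into a validated dataset: checks treatment codes
#' are dense integers 1..T forming a connected comparison network, and
#' optionally designates one outcome as mortality, which format-2 studies
#' model with a Poisson likelihood on person-years (death can occur once, so a
#' "patients with at least one event" count is an event count).
#'
#' @param studies list of [study_record()]s.
#' @param outcome_labels character vector naming outcomes 1..M.
#' @param treatment_labels optional character vector naming treatments 1..T
#'   (treatment 1 is the network reference).
#' @param mortality_outcome outcome index or label treated as death in
#'   format-2 studies, or `NULL` if none.
#' @return An object of class `"nma_dataset"` with elements `studies`,
#'   `n_treatments`, `n_outcomes`, `outcome_labels`, `treatment_labels`,
#'   `mortality_outcome` (integer or `NA`).
#' @export
nma_dataset <- function(studies, outcome_labels,
                        treatment_labels = NULL, mortality_outcome = NULL) {
  if (length(studies) == 0L) stop("no studies")
  M <- length(outcome_labels)
  treats <- sort(unique(unlist(lapply(studies, function(s)
    vapply(s$arms, function(a) a$treatment, integer(1))))))
  n_t <- max(treats)
  if (!identical(treats, seq_len(n_t)))
    stop("treatment codes must be dense integers 1..T; saw: ",
         paste(treats, collapse = ", "))
  for (s in studies) {
    if (max(s$reported_outcomes) > M)
      stop(sprintf("study %s: outcome index exceeds n_outcomes = %d",
                   s$study_id, M))
  }
  if (is.null(treatment_labels))
    treatment_labels <- paste0("treatment_", seq_len(n_t))
  if (is.character(mortality_outcome)) {
    mo <- match(mortality_outcome, outcome_labels)
    if (is.na(mo)) stop("mortality_outcome label not found: ", mortality_outcome)
    mortality_outcome <- mo
  }
  mortality_outcome <- if (is.null(mortality_outcome)) NA_integer_ else
    as.integer(mortality_outcome)
  # connectivity of the comparison network: studies are cliques of their arms
  edges <- do.call(rbind, lapply(studies, function(s) {
    tt <- unique(vapply(s$arms, function(a) a$treatment, integer(1)))
    if (length(tt) < 2L) return(NULL)
    t(utils::combn(tt, 2L))
  }))
  if (n_t > 1L) {
    if (is.null(edges)) stop("treatment network is disconnected")
    g <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2L), directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(seq_len(n_t)),
                                      igraph::V(g)$name))
    if (igraph::components(g)$no > 1L)
      stop("treatment network is disconnected")
  }
  structure(
    list(studies = studies, n_treatments = n_t, n_outcomes = M,
         outcome_labels = as.character(outcome_labels),
         treatment_labels = as.character(treatment_labels),
         mortality_outcome = mortality_outcome),
    class = "nma_dataset")
}

#' @export
print.nma_dataset <- function(x, ...) {
  fmt <- vapply(x$studies, function(s) s$data_format, integer(1))
  cat(sprintf("NMA dataset: %d studies (%d format-1, %d format-2, %d format-3)\n",
              length(x$studies), sum(fmt == 1), sum(fmt == 2), sum(fmt == 3)))
  cat(sprintf("  %d treatments (reference: %s), %d outcomes: %s\n",
              x$n_treatments, x$treatment_labels[1L], x$n_outcomes,
              paste(x$outcome_labels, collapse = ", ")))
  if (!is.na(x$mortality_outcome))
    cat(sprintf("  mortality outcome: %s\n",
                x$outcome_labels[x$mortality_outcome]))
  invisible(x)
}

required_columns <- c("study_id", "data_format", "arm", "treatment", "n",
                      "person_years", "mean_followup", "outcome", "count")

#' Read an NMA dataset from long-format CSV
#'
#' One row per (study, arm, outcome). Mandatory columns: `study_id`,
#' `data_format`, `arm`, `treatment`, `n`, `person_years`, `mean_followup`,
#' `outcome`, `count`. `person_years` or `mean_followup` may be empty (NA) per
#' arm, not both; an outcome a study does not report is an absent row, never a
#' zero. Outcomes may be labelled by name or index.
#'
#' @param path CSV file path.
#' @param outcome_labels optional explicit outcome ordering; defaults to order
#'   of first appearance.
#' @param mortality_outcome outcome label or index for death, or `NULL`.
#' @param treatment_labels optional treatment names (index 1 = reference).
#' @return An [nma_dataset()].
#' @export
read_nma <- function(path, outcome_labels = NULL, mortality_outcome = NULL,
                     treatment_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_columns, names(df))
  if (length(missing_cols) > 0L)
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(outcome_labels)) {
    outcome_labels <- as.character(unique(df$outcome))
  }
  df$outcome_idx <- match(as.character(df$outcome), outcome_labels)
  if (anyNA(df$outcome_idx))
    stop("unknown outcome label(s): ",
         paste(unique(df$outcome[is.na(df$outcome_idx)]), collapse = ", "))
  M <- length(outcome_labels)
  studies <- lapply(split(df, df$study_id)[unique(df$study_id)], function(sd) {
    fmt <- unique(sd$data_format)
    if (length(fmt) != 1L)
      stop(sprintf("study %s: inconsistent data_format", sd$study_id[1L]))
    arms <- lapply(split(sd, sd$arm)[as.character(sort(unique(sd$arm)))],
                   function(ad) {
      counts <- rep(NA_real_, M)
      counts[ad$outcome_idx] <- ad$count
      pick1 <- function(x, what) {
        u <- unique(x[!is.na(x)])
        if (length(u) > 1L)
          stop(sprintf("study %s arm %s: inconsistent %s",
                       ad$study_id[1L], ad$arm[1L], what))
        if (length(u) == 0L) NULL else u
      }
      arm_record(treatment = pick1(ad$treatment, "treatment"),
                 n = pick1(ad$n, "n"),
                 person_years = pick1(ad$person_years, "person_years"),
                 mean_followup = pick1(ad$mean_followup, "mean_followup"),
                 counts = counts)
    })
    study_record(sd$study_id[1L], fmt, unname(arms))
  })
  nma_dataset(unname(studies), outcome_labels = outcome_labels,
              treatment_labels = treatment_labels,
              mortality_outcome = mortality_outcome)
}

#' Convert a dataset back to its long tabular form
#'
#' @param x an [nma_dataset()].
#' @param ... unused.
#' @return A data.frame in the same layout [read_nma()] accepts.
#' @export
as.data.frame.nma_dataset <- function(x, ...) {
  rows <- lapply(x$studies, function(s) {
    do.call(rbind, lapply(seq_along(s$arms), function(k) {
      a <- s$arms[[k]]
      data.frame(study_id = s$study_id, data_format = s$data_format,
                 arm = k, treatment = a$treatment, n = a$n,
                 person_years = a$person_years,
                 mean_followup = a$mean_followup,
                 outcome = x$outcome_labels[s$reported_outcomes],
                 count = a$counts[s$reported_outcomes],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an NMA dataset as long-format CSV
#'
#' Inverse of [read_nma()]: `read_nma(write_nma(x, f))` reproduces all counts
#' and metadata.
#'
#' @param x an [nma_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nma <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
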