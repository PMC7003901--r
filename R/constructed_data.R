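#' Inflate event counts by a fixed factor
#'
#' The constructed-data stressor: multiply every event count by `factor`,
#' keeping patients, person-years and formats unchanged, and cap each
#' outcome's count at the number of patients in the arm. Because the
#' per-outcome cap can leave a format-1 arm with first-event counts summing
#' beyond `n` (impossible: each patient has at most one first event), such
#' arms are reconciled by proportionally scaling the capped counts back to
#' sum to `n` (largest-remainder rounding, preserving relative composition);
#' every reconciliation is reported via `message()`.
#'
#' @param dataset an [nma_dataset()].
#' @param factor positive integer inflation factor (1 = unchanged base case).
#' @return A new [nma_dataset()] with inflated counts.
#' @export
inflate <- function(dataset, factor) {
  if (!is.numeric(factor) || factor < 1) stop("inflation factor must be >= 1")
  studies <- lapply(dataset$studies, function(s) {
    arms <- lapply(seq_along(s$arms), function(k) {
      a <- s$arms[[k]]
      counts <- a$counts
      rep_m <- which(!is.na(counts))
      counts[rep_m] <- pmin(factor * counts[rep_m], a$n)
      if (s$data_format == 1L && sum(counts[rep_m]) > a$n) {
        counts[rep_m] <- largest_remainder_scale(counts[rep_m], a$n)
        message(sprintf(
          "inflate: study %s arm %d: capped first-event counts exceeded n = %d; proportionally reduced",
          s$study_id, k, a$n))
      }
      arm_record(a$treatment, a$n, person_years = a$person_years,
                 counts = counts)
    })
    study_record(s$study_id, s$data_format, arms)
  })
  nma_dataset(studies, outcome_labels = dataset$outcome_labels,
              treatment_labels = dataset$treatment_labels,
              mortality_outcome = if (is.na(dataset$mortality_outcome)) NULL
                                  else dataset$mortality_outcome)
}

# Scale a nonnegative integer vector to sum to `total`, rounding by largest
# remainder so the result is integer and preserves relative composition.
largest_remainder_scale <- function(x, total) {
  raw <- x * total / sum(x)
  out <- floor(raw)
  short <- as.integer(round(total - sum(out)))
  if (short > 0) {
    give <- order(raw - out, decreasing = TRUE)[seq_len(short)]
    out[give] <- out[give] + 1
  }
  out
}

#' Average event rate of an outcome
#'
#' Mean over all reporting arms and trials of the crude proportion
#' \eqn{r_{ikm}/n_{ik}}; the per-outcome summary used to track how the
#' constructed-data inflation moves a dataset's event rates.
#'
#' @param dataset an [nma_dataset()].
#' @param outcome outcome index or label.
#' @return Mean event proportion across reporting arms.
#' @export
average_event_rate <- function(dataset, outcome) {
  if (is.character(outcome)) {
    outcome <- match(outcome, dataset$outcome_labels)
    if (is.na(outcome)) stop("unknown outcome label")
  }
  props <- unlist(lapply(dataset$studies, function(s) {
    if (!outcome %in% s$reported_outcomes) return(NULL)
    vapply(s$arms, function(a) a$counts[outcome] / a$n, numeric(1))
  }))
  if (length(props) == 0L) stop("outcome reported by no study")
  mean(props)
}
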