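# Fixtures are constructed in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# A small two-study, two-outcome dataset covering formats 1 and 3.
make_toy_dataset <- function() {
  s1 <- study_record("trial_A", 1L, list(
    arm_record(1L, 100L, person_years = 95, counts = c(3, 5)),
    arm_record(2L, 100L, person_years = 97, counts = c(2, 4))))
  s2 <- study_record("trial_B", 3L, list(
    arm_record(1L, 120L, person_years = 120, counts = c(4, 7)),
    arm_record(3L, 120L, person_years = 118, counts = c(6, 3))))
  nma_dataset(list(s1, s2), outcome_labels = c("stroke", "bleed"))
}

# One single-format study with chosen hazards matrix laid alongside, for
# direct likelihood evaluation.
make_format_study <- function(format, counts_by_arm, n = 100L, E = 100,
                              treatments = c(1L, 2L)) {
  arms <- lapply(seq_along(counts_by_arm), function(k)
    arm_record(treatments[k], n, person_years = E,
               counts = counts_by_arm[[k]]))
  study_record(paste0("f", format, "_study"), format, arms)
}

# Random valid parameter values for a dataset (reference row zero).
rand_params <- function(dataset, centre = -2, sd = 0.5) {
  S <- length(dataset$studies)
  M <- dataset$n_outcomes
  Tn <- dataset$n_treatments
  baselines <- matrix(NA_real_, S, M)
  for (i in seq_len(S)) {
    m <- dataset$studies[[i]]$reported_outcomes
    baselines[i, m] <- stats::rnorm(length(m), centre, sd)
  }
  effects <- rbind(rep(0, M),
                   matrix(stats::rnorm((Tn - 1) * M, 0, sd), Tn - 1, M))
  model_params(baselines, effects)
}

# Deterministic synthetic analogue of an anticoagulant NMA: 8 two-arm RCTs
# (four active treatments, each tried twice against the reference) with four
# rare outcomes, mortality last, in all three data formats and realistically
# heterogeneous mean follow-up. Counts are the rounded expected values under
# a shared-hazard model, so the network carries a known signal; this is a
# SYNTHETIC stand-in, not extracted trial data.
make_synthetic_af <- function(n_arm = 9000L) {
  outcomes <- c("stroke", "mi", "death", "bleed")
  base_haz <- c(stroke = 0.006, mi = 0.004, death = 0.021, bleed = 0.012)
  true_hr <- rbind(
    c(1, 1, 1, 1),
    c(0.90, 0.83, 0.89, 0.81),
    c(0.75, 1.20, 0.89, 1.10),
    c(1.00, 0.94, 0.91, 0.88),
    c(0.92, 0.79, 0.82, 1.00))
  design <- data.frame(
    treat = c(2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    format = c(1L, 2L, 1L, 2L, 2L, 3L, 1L, 3L),
    followup = c(2, 2.5, 1.8, 3, 2, 2.2, 1.6, 2.8))
  studies <- lapply(seq_len(nrow(design)), function(i) {
    tr <- c(1L, design$treat[i])
    Tf <- design$followup[i]
    arms <- lapply(tr, function(t) {
      lam <- base_haz * true_hr[t, ]
      if (design$format[i] == 1L) {
        tot <- sum(lam)
        p_any <- -expm1(-tot * Tf)
        counts <- round(n_arm * p_any * lam / tot)
        E <- n_arm * p_any / tot  # expected exposure with censoring at event
        arm_record(t, n_arm, person_years = E, counts = counts)
      } else if (design$format[i] == 2L) {
        counts <- round(n_arm * -expm1(-lam * Tf))
        E <- n_arm * Tf
        counts["death"] <- round(E * lam["death"])
        arm_record(t, n_arm, person_years = E, counts = counts)
      } else {
        E <- n_arm * Tf
        arm_record(t, n_arm, person_years = E, counts = round(E * lam))
      }
    })
    study_record(sprintf("af_synth_%02d", i), design$format[i], arms)
  })
  nma_dataset(studies, outcome_labels = outcomes,
              treatment_labels = c("warfarin", "apix_like", "dabi_like",
                                   "edox_like", "riva_like"),
              mortality_outcome = "death")
}
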