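#' The fixed 10-trial simulation design
#'
#' Ten two-arm RCTs over three treatments, 100 patients per arm, one year of
#' follow-up, with data formats and treatment pairs fixed: trials 1-4 report
#' first-event counts (format 1), trials 5-7 patients-with-event counts
#' (format 2), trials 8-10 total event counts (format 3).
#'
#' @return data.frame with columns `study`, `data_format`, `treat_a`,
#'   `treat_b`.
#' @export
simulation_design <- function() {
  data.frame(
    study = 1:10,
    data_format = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    treat_a = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L, 1L, 1L),
    treat_b = c(2L, 3L, 2L, 3L, 2L, 3L, 3L, 3L, 3L, 2L))
}

#' Default true treatment effects of the simulation study
#'
#' Log hazard ratios versus treatment 1: treatment 2 is (-0.25, +0.25) on
#' outcomes (1, 2) and treatment 3 the mirror image (+0.25, -0.25).
#'
#' @return 3 x 2 matrix of log hazard ratios (row 1 zero by the reference
#'   constraint).
#' @export
default_true_effects <- function() {
  rbind(c(0, 0), c(-0.25, 0.25), c(0.25, -0.25))
}

#' One cell of the simulation design
#'
#' A scenario fixes the trial layout, the true log hazard ratios, and the
#' target average event (hazard) rate of each outcome; baselines are then
#' calibrated deterministically by [calibrate_baselines()].
#'
#' @param rate_outcome1,rate_outcome2 target average event rates, each drawn
#'   from \{0.05, 0.1, 0.2, 0.3, 0.4\} in the full 25-cell grid (other values
#'   in (0,1) are allowed for exploration).
#' @param true_effects treatments x outcomes matrix of log hazard ratios.
#' @param n_patients patients per arm.
#' @param followup follow-up in years.
#' @return An object of class `"nma_scenario"`.
#' @export
scenario_spec <- function(rate_outcome1, rate_outcome2,
                          true_effects = default_true_effects(),
                          n_patients = 100L, followup = 1) {
  stopifnot(rate_outcome1 > 0, rate_outcome1 < 1,
            rate_outcome2 > 0, rate_outcome2 < 1,
            all(true_effects[1L, ] == 0))
  structure(
    list(design = simulation_design(),
         true_effects = true_effects,
         target_rates = c(rate_outcome1, rate_outcome2),
         n_patients = as.integer(n_patients), followup = followup),
    class = "nma_scenario")
}

#' Calibrate per-trial baseline log hazards to the target rates
#'
#' For each trial and outcome the baseline \eqn{\omega_{im}} is set so that
#' the outcome's average event rate across the trial's two arms equals the
#' target exactly, with each arm's hazard following the consistency model for
#' that trial's treatment pair (\eqn{\lambda_b/\lambda_a = e^{\delta}},
#' \eqn{\delta = h_{t_b m} - h_{t_a m}}). On the default `"probability"`
#' scale the event rate of an arm is the crude proportion expected to
#' experience the outcome over follow-up, \eqn{p = 1 - e^{-\lambda T}}, the
#' same quantity the crude summary \eqn{r/n} estimates, and
#' \eqn{(p_a + p_b)/2 = \mathrm{rate}} is solved by a root-finder. On the
#' `"hazard"` scale the rate is the hazard itself and the solution is the
#' closed form \eqn{\omega = \log(2\,\mathrm{rate}/(1 + e^{\delta}))}; the
#' two coincide as rates become small.
#'
#' @param scenario an [scenario_spec()].
#' @param scale `"probability"` (default) or `"hazard"`.
#' @return trials x outcomes matrix of baseline log hazards.
#' @export
calibrate_baselines <- function(scenario,
                                scale = c("probability", "hazard")) {
  scale <- match.arg(scale)
  des <- scenario$design
  h <- scenario$true_effects
  Tf <- scenario$followup
  M <- length(scenario$target_rates)
  omega <- matrix(NA_real_, nrow(des), M)
  for (i in seq_len(nrow(des))) {
    for (m in seq_len(M)) {
      delta <- h[des$treat_b[i], m] - h[des$treat_a[i], m]
      rate <- scenario$target_rates[m]
      if (scale == "hazard") {
        omega[i, m] <- log(2 * rate / (1 + exp(delta)))
      } else {
        mean_p <- function(w) {
          lam <- exp(w)
          (-expm1(-lam * Tf) - expm1(-lam * exp(delta) * Tf)) / 2 - rate
        }
        omega[i, m] <- stats::uniroot(mean_p, c(log(rate) - 5, 5),
                                      tol = 1e-12)$root
      }
    }
  }
  omega
}

#' Simulate one trial from latent exponential event times
#'
#' All formats share the same generating process: each patient has
#' independent latent exponential event times, one per outcome, at the arm's
#' hazards. The format determines the summary:
#' \describe{
#'   \item{format 1}{only the first event before end of follow-up is
#'     recorded and the patient is then censored; person-years are the
#'     *realized* exposure \eqn{\sum_i \min(\text{first event}, T)};}
#'   \item{format 2}{each outcome is summarized marginally as patients with
#'     at least one event, \eqn{r \sim \mathrm{Bin}(n, 1 - e^{-\lambda T})},
#'     with full exposure \eqn{E = nT};}
#'   \item{format 3}{total events including repeats,
#'     \eqn{r \sim \mathrm{Poisson}(nT\lambda)}, with \eqn{E = nT}.}
#' }
#' Uses the current RNG state; seed via `set.seed()` upstream.
#'
#' @param study_id identifier for the resulting study record.
#' @param data_format 1, 2 or 3.
#' @param treatments integer vector of the two arms' treatment codes.
#' @param hazards arms x outcomes matrix of true hazards.
#' @param n_patients patients per arm.
#' @param followup follow-up in years.
#' @return A [study_record()].
#' @export
simulate_trial <- function(study_id, data_format, treatments, hazards,
                           n_patients = 100L, followup = 1) {
  M <- ncol(hazards)
  arms <- lapply(seq_along(treatments), function(k) {
    lam <- hazards[k, ]
    if (data_format == 1L) {
      # competing exponentials: first event wins, censor at followup
      times <- matrix(Inf, n_patients, M)
      for (m in seq_len(M)) {
        if (lam[m] > 0) times[, m] <- stats::rexp(n_patients, lam[m])
      }
      first_t <- do.call(pmin, asplit(times, 2L))
      first_m <- max.col(-times, ties.method = "first")
      observed <- first_t < followup
      counts <- vapply(seq_len(M),
                       function(m) sum(observed & first_m == m), numeric(1))
      E <- sum(pmin(first_t, followup))
      arm_record(treatments[k], n_patients, person_years = E, counts = counts)
    } else if (data_format == 2L) {
      counts <- stats::rbinom(M, n_patients, -expm1(-lam * followup))
      arm_record(treatments[k], n_patients,
                 person_years = n_patients * followup, counts = counts)
    } else {
      counts <- stats::rpois(M, n_patients * followup * lam)
      arm_record(treatments[k], n_patients,
                 person_years = n_patients * followup, counts = counts)
    }
  })
  study_record(study_id, data_format, arms)
}

#' Simulate a full 10-trial dataset for one scenario
#'
#' Calibrates baselines, computes each arm's true hazards from the
#' consistency model, and simulates every trial of the design. Uses the
#' current RNG state.
#'
#' @param scenario an [scenario_spec()].
#' @return An [nma_dataset()] with two outcomes and no mortality outcome.
#' @export
simulate_scenario <- function(scenario) {
  des <- scenario$design
  h <- scenario$true_effects
  omega <- calibrate_baselines(scenario)
  M <- length(scenario$target_rates)
  studies <- lapply(seq_len(nrow(des)), function(i) {
    tr <- c(des$treat_a[i], des$treat_b[i])
    lam <- matrix(NA_real_, 2L, M)
    for (k in 1:2) {
      for (m in seq_len(M)) {
        lam[k, m] <- exp(omega[i, m] + h[tr[k], m] - h[tr[1L], m])
      }
    }
    simulate_trial(des$study[i], des$data_format[i], tr, lam,
                   scenario$n_patients, scenario$followup)
  })
  nma_dataset(studies, outcome_labels = paste0("outcome_", seq_len(M)))
}

#' Model roster for simulation runs
#'
#' Convenience constructor for the model list [run_scenario()] fits per
#' replicate: each entry names a model ("shared" or "simple") and its prior.
#'
#' @param name label used in results.
#' @param model `"shared"` or `"simple"`.
#' @param prior a [prior_spec()]; `NULL` for the model's default.
#' @return A list suitable as one element of `models` in [run_scenario()].
#' @export
model_choice <- function(name, model = c("shared", "simple"), prior = NULL) {
  model <- match.arg(model)
  list(name = name, model = model, prior = prior)
}

#' Run one simulation-study cell
#'
#' For each replicate: simulate the 10 trials, fit every model in `models`
#' to the *same* dataset, and record the posterior mean and 95% credible
#' interval of each non-reference log effect. Performance per model and
#' outcome pools treatments 2 and 3:
#' bias is the mean of \eqn{\hat h_{kml} - h_{km}} over the
#' \eqn{2 n_{\mathrm{sim}}} (treatment, replicate) pairs (the variant summed
#' over treatments but divided by \eqn{n_{\mathrm{sim}}} only is also
#' reported as `bias_sum_k`); coverage is the proportion of intervals
#' containing the truth, with binomial Monte-Carlo standard error
#' \eqn{\sqrt{c(1-c)/N}}. Replicates where a model fails (e.g. the simple
#' model meets a format-3 count above `n`) are logged with their seeds and
#' excluded from that model's summaries, never silently dropped.
#'
#' @param scenario an [scenario_spec()].
#' @param models list of [model_choice()]s.
#' @param n_sim number of replicates.
#' @param control an [mcmc_control()] used for every fit (its seed is
#'   overwritten per replicate).
#' @param master_seed integer; drives the whole run. Identical master seeds
#'   give identical results.
#' @return An object of class `"nma_performance"`: `performance` data.frame
#'   (model, outcome, bias, bias_sum_k, mc_se_bias, coverage, mc_se_coverage,
#'   n_completed, n_failed), `estimates` (per-replicate long data.frame), and
#'   `failures` (replicate, model, seed, message).
#' @export
run_scenario <- function(scenario, models, n_sim, control = mcmc_control(),
                         master_seed = 1L) {
  stopifnot(n_sim >= 1L)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
  h <- scenario$true_effects
  n_treat <- nrow(h)
  M <- ncol(h)
  est <- vector("list", n_sim * length(models))
  failures <- list()
  idx <- 0L
  for (l in seq_len(n_sim)) {
    set.seed(seeds[l])
    dataset <- simulate_scenario(scenario)
    for (mod in models) {
      ctl <- control
      ctl$seed <- (seeds[l] + 1L) %% (.Machine$integer.max - 1L) + 1L
      fit <- tryCatch(
        fit_nma(dataset, model = mod$model, prior = mod$prior, control = ctl),
        error = function(e) e)
      idx <- idx + 1L
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          replicate = l, model = mod$name, seed = seeds[l],
          message = conditionMessage(fit), stringsAsFactors = FALSE)
        next
      }
      tab <- fit$effects$table
      est[[idx]] <- data.frame(
        replicate = l, model = mod$name,
        treatment = fit$summary$treatment[fit$summary$kind == "effect"],
        outcome = fit$summary$outcome[fit$summary$kind == "effect"],
        estimate = tab$mean, lower = tab$q2.5, upper = tab$q97.5,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, est)
  perf <- do.call(rbind, lapply(unique(est$model), function(mn) {
    do.call(rbind, lapply(seq_len(M), function(m) {
      e <- est[est$model == mn & est$outcome == m, ]
      truth <- h[cbind(e$treatment, e$outcome)]
      err <- e$estimate - truth
      covered <- e$lower <= truth & truth <= e$upper
      n_rep <- length(unique(e$replicate))
      data.frame(
        model = mn, outcome = m,
        bias = mean(err),
        bias_sum_k = sum(err) / n_rep,
        mc_se_bias = stats::sd(err) / sqrt(length(err)),
        coverage = mean(covered),
        mc_se_coverage = sqrt(mean(covered) * (1 - mean(covered)) /
                                length(covered)),
        n_completed = n_rep,
        n_failed = n_sim - n_rep,
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(perf) <- NULL
  structure(list(performance = perf, estimates = est,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 scenario = scenario, master_seed = master_seed,
                 seeds = seeds, n_sim = n_sim),
            class = "nma_performance")
}

#' @export
print.nma_performance <- function(x, ...) {
  cat(sprintf("Simulation cell: target rates (%.2f, %.2f), %d replicates\n",
              x$scenario$target_rates[1L], x$scenario$target_rates[2L],
              x$n_sim))
  print(x$performance, row.names = FALSE, digits = 3)
  if (!is.null(x$failures))
    cat(sprintf("%d replicate-level failures (see $failures)\n",
                nrow(x$failures)))
  invisible(x)
}

#' Replicates needed for target Monte-Carlo precision
#'
#' The standard planning formulas: bias needs
#' \eqn{n \ge \sigma^2 / \mathrm{MCSE}^2} replicates for an assumed
#' per-replicate estimator SD, and coverage at nominal level \eqn{p} needs
#' \eqn{n \ge p(1-p)/\mathrm{MCSE}^2}; the requirement is the maximum.
#'
#' @param bias_mcse_target target Monte-Carlo SE of the bias.
#' @param assumed_sd assumed SD of a single replicate's estimate.
#' @param nominal_coverage nominal interval coverage (e.g. 0.95).
#' @param coverage_mcse_target target Monte-Carlo SE of the coverage.
#' @return Required number of replicates (integer).
#' @export
required_nsim <- function(bias_mcse_target, assumed_sd, nominal_coverage,
                          coverage_mcse_target) {
  stopifnot(bias_mcse_target > 0, coverage_mcse_target > 0)
  p <- nominal_coverage
  # tolerant ceiling so exact-ratio targets are not bumped by float noise
  ceil_tol <- function(x) as.integer(ceiling(x - 1e-9 * max(1, x)))
  max(ceil_tol(assumed_sd^2 / bias_mcse_target^2),
      ceil_tol(p * (1 - p) / coverage_mcse_target^2))
}
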