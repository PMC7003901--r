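#' Prior specification
#'
#' Independent mean-zero normal priors parameterized by *precision* (inverse
#' variance), the convention of the BUGS family of samplers: a precision of
#' 0.5 is a standard deviation of about 1.41. Defaults are the shared-model
#' priors; use `prior_spec(1e-4, 1e-4)` (sd 100) for the simple odds-ratio
#' model and `prior_spec(0.05, 0.05)` (sd about 4.47) for the vague variant.
#'
#' @param baseline_precision precision of the per-study baseline priors.
#' @param effect_precision precision of the treatment-effect priors.
#' @return An object of class `"nma_prior"`.
#' @export
prior_spec <- function(baseline_precision = 0.5, effect_precision = 0.5) {
  stopifnot(baseline_precision > 0, effect_precision > 0)
  structure(list(baseline_precision = baseline_precision,
                 effect_precision = effect_precision),
            class = "nma_prior")
}

#' Model parameters
#'
#' Baselines are per study and outcome (log baseline hazard \eqn{\omega_{im}}
#' for the shared model, log baseline odds \eqn{\mu_{im}} for the simple
#' model); effects are per treatment and outcome (log hazard ratios
#' \eqn{h_{tm}} or log odds ratios \eqn{d_{tm}} versus treatment 1). The
#' first effect row is pinned at zero: treatment 1 is the reference.
#'
#' @param baselines numeric matrix, studies x outcomes; `NA` allowed where a
#'   study does not report an outcome.
#' @param effects numeric matrix, treatments x outcomes, row 1 all zero.
#' @return An object of class `"nma_params"`.
#' @export
model_params <- function(baselines, effects) {
  baselines <- as.matrix(baselines)
  effects <- as.matrix(effects)
  if (any(effects[1L, ] != 0))
    stop("reference constraint violated: effects[1, ] must be 0")
  if (ncol(baselines) != ncol(effects))
    stop("baselines and effects disagree on the number of outcomes")
  structure(list(baselines = baselines, effects = effects),
            class = "nma_params")
}

#' Linear predictor of the network model
#'
#' The fixed-effect consistency model on the log hazard (or log odds) scale:
#' \deqn{\log \lambda_{ikm} = \omega_{im} + h_{t_{ik} m} - h_{t_{i1} m}}
#' where \eqn{t_{i1}} is the treatment of the trial's first arm, so relative
#' effects in trials without a reference arm follow from consistency.
#'
#' @param params a [model_params()].
#' @param study_index row of `params$baselines` for this study.
#' @param treatment treatment code of the arm.
#' @param outcome outcome index.
#' @param base_treatment treatment of the trial's first arm.
#' @return Log hazard (shared model) or log odds (simple model).
#' @export
linear_predictor <- function(params, study_index, treatment, outcome,
                             base_treatment) {
  eff <- params$effects
  if (treatment > nrow(eff) || base_treatment > nrow(eff))
    stop("unknown treatment code")
  if (outcome > ncol(eff)) stop("unknown outcome index")
  params$baselines[study_index, outcome] +
    eff[treatment, outcome] - eff[base_treatment, outcome]
}

#' Per-study hazard (or odds) matrix
#'
#' Evaluates the linear predictor for every arm and reported outcome of one
#' study and exponentiates, giving the arm x outcome hazard matrix the
#' format-specific likelihoods consume (columns for unreported outcomes are
#' `NA`).
#'
#' @param params a [model_params()].
#' @param dataset an [nma_dataset()].
#' @param study_index which study.
#' @return Numeric matrix arms x outcomes of hazards \eqn{\lambda_{ikm}}.
#' @export
study_hazards <- function(params, dataset, study_index) {
  s <- dataset$studies[[study_index]]
  bt <- s$arms[[1L]]$treatment
  M <- dataset$n_outcomes
  lam <- matrix(NA_real_, nrow = length(s$arms), ncol = M)
  for (k in seq_along(s$arms)) {
    tk <- s$arms[[k]]$treatment
    for (m in s$reported_outcomes) {
      lam[k, m] <- exp(linear_predictor(params, study_index, tk, m, bt))
    }
  }
  lam
}

#' Format-1 log-likelihood: competing-risks first-event counts
#'
#' Patients are censored at their first event, so per arm the total count
#' \eqn{R = \sum_m r_m} is Poisson with mean \eqn{E \sum_m \lambda_m} and the
#' split over outcomes is multinomial with probabilities
#' \eqn{\lambda_m / \sum_l \lambda_l}:
#' \deqn{R_{ik} \sim \mathrm{Poisson}(E_{ik} \textstyle\sum_m \lambda_{ikm}),
#'   \quad r_{ik\cdot} \sim \mathrm{Multinomial}(\lambda_{ik\cdot}/
#'   \textstyle\sum_m \lambda_{ikm},\; R_{ik}).}
#' By the multinomial-Poisson factorization this density equals the product of
#' independent Poissons \eqn{\prod_m \mathrm{Poisson}(r_m; E\lambda_m)}; the
#' structural form is evaluated here so the competing-risks decomposition is
#' explicit.
#'
#' @param study a format-1 [study_record()].
#' @param hazards arms x outcomes matrix of positive hazards.
#' @return Log-likelihood contribution of the study.
#' @export
loglik_format1 <- function(study, hazards) {
  if (study$data_format != 1L) stop("study is not data format 1")
  ll <- 0
  for (k in seq_along(study$arms)) {
    a <- study$arms[[k]]
    m <- study$reported_outcomes
    lam <- hazards[k, m]
    if (any(!is.finite(lam)) || any(lam <= 0))
      stop("hazards must be strictly positive for all reported outcomes")
    r <- a$counts[m]
    R <- sum(r)
    tot <- sum(lam)
    ll <- ll + stats::dpois(R, exposure(a) * tot, log = TRUE)
    if (R > 0)
      ll <- ll + stats::dmultinom(r, size = R, prob = lam / tot, log = TRUE)
  }
  ll
}

#' Format-2 log-likelihood: patients with at least one event
#'
#' Non-mortality outcomes are binomial in the number randomized with the
#' complementary log-log link tying the per-patient event probability over the
#' mean follow-up \eqn{\bar T} to the hazard:
#' \deqn{r \sim \mathrm{Bin}(p, n), \quad
#'   \mathrm{cloglog}(p) = \log \bar T + \log \lambda
#'   \iff p = 1 - e^{-\lambda \bar T}.}
#' A designated mortality outcome (which can occur at most once per patient,
#' so its count is an event count) is Poisson on person-years:
#' \eqn{r_M \sim \mathrm{Poisson}(E \lambda_M)}.
#'
#' @param study a format-2 [study_record()].
#' @param hazards arms x outcomes matrix of positive hazards.
#' @param mortality_outcome outcome index modelled as death, or `NA`/`NULL`.
#' @return Log-likelihood contribution of the study.
#' @export
loglik_format2 <- function(study, hazards, mortality_outcome = NA) {
  if (study$data_format != 2L) stop("study is not data format 2")
  if (is.null(mortality_outcome)) mortality_outcome <- NA_integer_
  ll <- 0
  for (k in seq_along(study$arms)) {
    a <- study$arms[[k]]
    for (m in study$reported_outcomes) {
      lam <- hazards[k, m]
      if (!is.finite(lam) || lam <= 0)
        stop("hazards must be strictly positive for all reported outcomes")
      r <- a$counts[m]
      if (!is.na(mortality_outcome) && m == mortality_outcome) {
        ll <- ll + stats::dpois(r, exposure(a) * lam, log = TRUE)
      } else {
        if (r > a$n)
          stop(sprintf("study %s arm %d outcome %d: r = %d > n = %d",
                       study$study_id, k, m, as.integer(r), a$n))
        p <- -expm1(-lam * a$mean_followup)
        ll <- ll + stats::dbinom(r, a$n, p, log = TRUE)
      }
    }
  }
  ll
}

#' Format-3 log-likelihood: total event counts
#'
#' Total events of each outcome, repeats included, are Poisson on
#' person-years: \eqn{r \sim \mathrm{Poisson}(E \lambda)}, independently
#' across outcomes.
#'
#' @param study a format-3 [study_record()].
#' @param hazards arms x outcomes matrix of positive hazards.
#' @return Log-likelihood contribution of the study.
#' @export
loglik_format3 <- function(study, hazards) {
  if (study$data_format != 3L) stop("study is not data format 3")
  ll <- 0
  for (k in seq_along(study$arms)) {
    a <- study$arms[[k]]
    m <- study$reported_outcomes
    lam <- hazards[k, m]
    if (any(!is.finite(lam)) || any(lam <= 0))
      stop("hazards must be strictly positive for all reported outcomes")
    ll <- ll + sum(stats::dpois(a$counts[m], exposure(a) * lam, log = TRUE))
  }
  ll
}

#' Shared-parameter model log-likelihood
#'
#' Sums the format-specific blocks over all studies: every format contributes
#' evidence about the same hazards \eqn{\lambda_{ikm}}, hence about the same
#' log hazard ratios.
#'
#' @param dataset an [nma_dataset()].
#' @param params a [model_params()] on the log-hazard scale.
#' @return Total log-likelihood.
#' @export
loglik_shared <- function(dataset, params) {
  ll <- 0
  for (i in seq_along(dataset$studies)) {
    s <- dataset$studies[[i]]
    lam <- study_hazards(params, dataset, i)
    ll <- ll + switch(s$data_format,
      loglik_format1(s, lam),
      loglik_format2(s, lam, dataset$mortality_outcome),
      loglik_format3(s, lam))
  }
  ll
}

#' Simple odds-ratio model log-likelihood
#'
#' Treats every count, regardless of data format, as the number of patients
#' with the event out of `n` randomized, binomial with a logit link:
#' \deqn{r \sim \mathrm{Bin}(p, n), \quad
#'   \mathrm{logit}(p) = \mu_{im} + d_{t_{ik} m} - d_{t_{i1} m}.}
#' Outcomes are modelled independently; follow-up and competing risks are
#' ignored by construction. A count exceeding `n` (possible for format-3
#' total-event counts at high rates) is a domain error, surfaced rather than
#' clipped.
#'
#' @param dataset an [nma_dataset()].
#' @param params a [model_params()] on the log-odds scale.
#' @return Total log-likelihood.
#' @export
loglik_simple <- function(dataset, params) {
  ll <- 0
  for (i in seq_along(dataset$studies)) {
    s <- dataset$studies[[i]]
    bt <- s$arms[[1L]]$treatment
    for (k in seq_along(s$arms)) {
      a <- s$arms[[k]]
      for (m in s$reported_outcomes) {
        r <- a$counts[m]
        if (r > a$n)
          stop(sprintf(
            "simple model domain error: study %s arm %d outcome %d: r = %d > n = %d",
            s$study_id, k, m, as.integer(r), a$n))
        p <- stats::plogis(linear_predictor(params, i, a$treatment, m, bt))
        ll <- ll + stats::dbinom(r, a$n, p, log = TRUE)
      }
    }
  }
  ll
}

#' Log prior density
#'
#' Independent mean-zero normals on every modelled baseline and every
#' non-reference effect; reference effects (row 1) are constants and
#' contribute nothing.
#'
#' @param params a [model_params()].
#' @param prior a [prior_spec()].
#' @return Log prior density.
#' @export
log_prior <- function(params, prior) {
  sd_b <- 1 / sqrt(prior$baseline_precision)
  sd_e <- 1 / sqrt(prior$effect_precision)
  b <- params$baselines[!is.na(params$baselines)]
  e <- params$effects[-1L, , drop = FALSE]
  sum(stats::dnorm(b, 0, sd_b, log = TRUE)) +
    sum(stats::dnorm(e, 0, sd_e, log = TRUE))
}
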