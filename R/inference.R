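#' MCMC run configuration
#'
#' Two or more chains of componentwise adaptive random-walk Metropolis.
#' Defaults (2 chains, 2000 burn-in, 4000 kept draws per chain) are sized for
#' the package's sampler, whose per-iteration cost is a handful of likelihood
#' cells; `compat = "bugs"` switches to the long two-chain protocol
#' traditional for Gibbs-sampler engines (60000 burn-in, 30000 samples).
#'
#' @param n_chains number of chains (>= 2 so split-free convergence
#'   diagnostics are defined).
#' @param burn_in discarded iterations per chain.
#' @param samples kept iterations per chain.
#' @param seed integer seed; mandatory for every stochastic run.
#' @param rhat_threshold flag the fit as non-converged if any parameter's
#'   potential scale reduction exceeds this.
#' @param compat `"none"` or `"bugs"` (overrides `burn_in`/`samples` with the
#'   60000/30000 protocol).
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 2L, burn_in = 2000L, samples = 4000L,
                         seed = 1L, rhat_threshold = 1.05,
                         compat = c("none", "bugs")) {
  compat <- match.arg(compat)
  if (compat == "bugs") {
    burn_in <- 60000L
    samples <- 30000L
  }
  stopifnot(n_chains >= 2L, burn_in > 0L, samples > 0L)
  if (is.null(seed) || is.na(seed)) stop("an integer seed is required")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 samples = as.integer(samples), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

# Flatten a dataset + model choice into likelihood "cells" for the C++
# log-posterior: one cell per (arm, reported outcome). Format-1 studies enter
# as per-outcome Poisson cells (exact multinomial-Poisson factorization).
compile_model <- function(dataset, model = c("shared", "simple")) {
  model <- match.arg(model)
  S <- length(dataset$studies)
  M <- dataset$n_outcomes
  Tn <- dataset$n_treatments
  b_idx <- matrix(NA_integer_, S, M)
  nb <- 0L
  for (i in seq_len(S)) {
    for (m in dataset$studies[[i]]$reported_outcomes) {
      nb <- nb + 1L
      b_idx[i, m] <- nb
    }
  }
  b <- t <- bt <- mm <- type <- integer(0)
  r <- n <- E <- Tb <- numeric(0)
  for (i in seq_len(S)) {
    s <- dataset$studies[[i]]
    base_t <- s$arms[[1L]]$treatment
    for (k in seq_along(s$arms)) {
      a <- s$arms[[k]]
      for (m in s$reported_outcomes) {
        if (model == "simple") {
          if (a$counts[m] > a$n)
            stop(sprintf(
              "simple model domain error: study %s arm %d outcome %d: r = %d > n = %d",
              s$study_id, k, m, as.integer(a$counts[m]), a$n))
          ty <- 3L
        } else {
          mort <- !is.na(dataset$mortality_outcome) &&
            m == dataset$mortality_outcome
          ty <- if (s$data_format == 2L && !mort) 2L else 1L
        }
        b <- c(b, b_idx[i, m] - 1L)  # 0-based for C++
        t <- c(t, a$treatment)
        bt <- c(bt, base_t)
        mm <- c(mm, m)
        type <- c(type, ty)
        r <- c(r, a$counts[m])
        n <- c(n, a$n)
        E <- c(E, exposure(a))
        Tb <- c(Tb, a$mean_followup)
      }
    }
  }
  n_par <- nb + (Tn - 1L) * M
  eff_t <- eff_m <- integer(0)
  if (Tn > 1L) {
    eff_t <- rep(2:Tn, times = M)
    eff_m <- rep(seq_len(M), each = Tn - 1L)
  }
  # cells touched by each parameter (1-based cell indices)
  affected <- vector("list", n_par)
  for (p in seq_len(nb)) affected[[p]] <- which(b == p - 1L)
  for (j in seq_along(eff_t)) {
    tj <- eff_t[j]
    affected[[nb + j]] <- which(mm == eff_m[j] & ((t == tj) != (bt == tj)))
  }
  kind <- if (model == "shared") c("omega", "h") else c("mu", "d")
  bpos <- which(!is.na(b_idx), arr.ind = TRUE)
  bpos <- bpos[order(b_idx[!is.na(b_idx)]), , drop = FALSE]
  param_info <- data.frame(
    name = c(sprintf("%s[%d,%d]", kind[1L], bpos[, 1L], bpos[, 2L]),
             if (length(eff_t)) sprintf("%s[%d,%d]", kind[2L], eff_t, eff_m)),
    kind = c(rep("baseline", nb), rep("effect", length(eff_t))),
    study = c(bpos[, 1L], rep(NA_integer_, length(eff_t))),
    treatment = c(rep(NA_integer_, nb), eff_t),
    outcome = c(bpos[, 2L], eff_m),
    stringsAsFactors = FALSE)
  list(spec = list(b = b, t = t, bt = bt, m = mm, type = type, r = r, n = n,
                   E = E, Tbar = Tb, n_b = nb, n_treat = Tn, n_out = M),
       affected = affected, param_info = param_info, model = model,
       b_idx = b_idx)
}

# Empirical starting values: baselines at the crude log rate (0.5-event
# continuity correction for initialization only), effects at 0.
initial_values <- function(dataset, compiled) {
  nb <- compiled$spec$n_b
  init <- numeric(nrow(compiled$param_info))
  for (i in seq_along(dataset$studies)) {
    s <- dataset$studies[[i]]
    for (m in s$reported_outcomes) {
      p <- compiled$b_idx[i, m]
      rr <- sum(vapply(s$arms, function(a) a$counts[m], numeric(1)))
      if (compiled$model == "shared") {
        ee <- sum(vapply(s$arms, exposure, numeric(1)))
        init[p] <- log((rr + 0.5) / ee)
      } else {
        nn <- sum(vapply(s$arms, function(a) a$n, numeric(1)))
        init[p] <- stats::qlogis((rr + 0.5) / (nn + 1))
      }
    }
  }
  init
}

#' Potential scale reduction (Brooks-Gelman-Rubin) statistic
#'
#' The classic between/within-chain variance ratio for one parameter:
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}}. Values near 1 indicate
#' the chains have mixed; 1 exactly when the chain means coincide.
#'
#' @param chains matrix (iterations x chains) or list of equal-length numeric
#'   vectors, one per chain.
#' @return The \eqn{\hat R} statistic (numeric scalar).
#' @export
rhat <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("at least 2 chains are required")
  n <- nrow(chains)
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize treatment-effect draws as hazard or odds ratios
#'
#' Posterior mean, sd and equal-tailed 95% interval of each log effect and of
#' its exponential (the ratio scale summaries are summaries of `exp(draws)`,
#' not exponentiated summaries), plus the across-outcome correlation matrix of
#' each treatment's effect draws. Degenerate draws (zero variance) yield `NA`
#' correlations and are flagged.
#'
#' @param draws numeric matrix of pooled posterior draws, one column per
#'   non-reference (treatment, outcome) effect.
#' @param treatment integer vector: treatment code of each column.
#' @param outcome integer vector: outcome index of each column.
#' @param treatment_labels,outcome_labels optional names used in the output.
#' @return List with `table` (one row per effect) and `correlations` (one
#'   outcome x outcome matrix per treatment).
#' @export
summarize_effects <- function(draws, treatment, outcome,
                              treatment_labels = NULL, outcome_labels = NULL) {
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) == length(treatment), length(treatment) == length(outcome))
  if (is.null(treatment_labels))
    treatment_labels <- paste0("treatment_", seq_len(max(treatment)))
  if (is.null(outcome_labels))
    outcome_labels <- paste0("outcome_", seq_len(max(outcome)))
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  hr <- exp(draws)
  tab <- data.frame(
    treatment = treatment_labels[treatment],
    outcome = outcome_labels[outcome],
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    q2.5 = apply(draws, 2L, q, 0.025),
    q97.5 = apply(draws, 2L, q, 0.975),
    hr_mean = colMeans(hr),
    hr_sd = apply(hr, 2L, stats::sd),
    hr_q2.5 = apply(hr, 2L, q, 0.025),
    hr_q97.5 = apply(hr, 2L, q, 0.975),
    stringsAsFactors = FALSE)
  tab$degenerate <- tab$sd == 0
  correlations <- lapply(sort(unique(treatment)), function(tt) {
    cols <- which(treatment == tt)
    mats <- draws[, cols, drop = FALSE]
    colnames(mats) <- outcome_labels[outcome[cols]]
    if (any(apply(mats, 2L, stats::sd) == 0)) {
      cm <- matrix(NA_real_, ncol(mats), ncol(mats),
                   dimnames = list(colnames(mats), colnames(mats)))
      diag(cm) <- 1
      cm
    } else {
      stats::cor(mats)
    }
  })
  names(correlations) <- treatment_labels[sort(unique(treatment))]
  list(table = tab, correlations = correlations)
}

#' Fit an NMA model by MCMC
#'
#' Samples the posterior of the shared-parameter hazard-ratio model or the
#' simple odds-ratio model. Chains start from empirical crude-rate baselines
#' (later chains jittered) and are run with componentwise adaptive
#' random-walk Metropolis; convergence is assessed by the potential scale
#' reduction statistic for every parameter and the fit is flagged (never
#' silently rerun) if any exceeds the threshold.
#'
#' @param dataset an [nma_dataset()].
#' @param model `"shared"` (log hazard ratios) or `"simple"` (log odds
#'   ratios).
#' @param prior a [prior_spec()]; defaults to precision 0.5 for the shared
#'   model and 1e-4 for the simple model.
#' @param control an [mcmc_control()].
#' @return An object of class `"nma_fit"`: `summary` (per-parameter posterior
#'   mean/sd/quantiles/rhat), `effects` (ratio-scale summaries and
#'   correlations from [summarize_effects()]), `draws` (iterations x chains x
#'   parameters array), `converged` flag, and the inputs.
#' @export
fit_nma <- function(dataset, model = c("shared", "simple"), prior = NULL,
                    control = mcmc_control()) {
  model <- match.arg(model)
  if (is.null(prior)) {
    prior <- if (model == "shared") prior_spec(0.5, 0.5) else
      prior_spec(1e-4, 1e-4)
  }
  compiled <- compile_model(dataset, model)
  nb <- compiled$spec$n_b
  n_par <- nrow(compiled$param_info)
  prior_prec <- c(rep(prior$baseline_precision, nb),
                  rep(prior$effect_precision, n_par - nb))
  init0 <- initial_values(dataset, compiled)
  set.seed(control$seed)
  draws <- array(NA_real_, c(control$samples, control$n_chains, n_par),
                 dimnames = list(NULL, NULL, compiled$param_info$name))
  acc <- matrix(NA_real_, control$n_chains, n_par)
  for (ch in seq_len(control$n_chains)) {
    init <- if (ch == 1L) init0 else init0 + stats::rnorm(n_par, 0, 0.25)
    run <- mcmc_cw(compiled$spec, compiled$affected, prior_prec, init,
                   control$burn_in, control$samples)
    draws[, ch, ] <- run$draws
    acc[ch, ] <- run$acceptance
  }
  rh <- vapply(seq_len(n_par), function(p) rhat(draws[, , p]), numeric(1))
  pooled <- matrix(draws, ncol = n_par)
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summary_df <- cbind(
    compiled$param_info,
    data.frame(mean = colMeans(pooled), sd = apply(pooled, 2L, stats::sd),
               q2.5 = apply(pooled, 2L, q, 0.025),
               q97.5 = apply(pooled, 2L, q, 0.975),
               rhat = rh))
  eff_cols <- which(compiled$param_info$kind == "effect")
  effects <- summarize_effects(
    pooled[, eff_cols, drop = FALSE],
    compiled$param_info$treatment[eff_cols],
    compiled$param_info$outcome[eff_cols],
    treatment_labels = dataset$treatment_labels,
    outcome_labels = dataset$outcome_labels)
  effects$table$rhat <- rh[eff_cols]
  structure(
    list(model = model, prior = prior, control = control,
         summary = summary_df, effects = effects, draws = draws,
         acceptance = acc, converged = all(rh <= control$rhat_threshold),
         reference = dataset$treatment_labels[1L]),
    class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  scale <- if (x$model == "shared") "hazard ratio" else "odds ratio"
  cat(sprintf("%s-model NMA fit (%s scale, relative to %s)\n",
              x$model, scale, x$reference))
  cat(sprintf("  %d chains x %d draws; converged: %s (max rhat %.3f)\n",
              x$control$n_chains, x$control$samples, x$converged,
              max(x$summary$rhat)))
  tab <- x$effects$table
  print(data.frame(treatment = tab$treatment, outcome = tab$outcome,
                   ratio = sprintf("%.3f (%.3f, %.3f)", tab$hr_mean,
                                   tab$hr_q2.5, tab$hr_q97.5),
                   rhat = round(tab$rhat, 3)), row.names = FALSE)
  invisible(x)
}
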