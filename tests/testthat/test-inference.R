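test_that("potential scale reduction is 1 for identical chains, large for split ones", {
  x <- rnorm(500)
  # with zero between-chain variance the statistic is sqrt((n-1)/n), i.e. 1
  # up to the finite-sample factor
  expect_equal(rhat(cbind(x, x)), 1, tolerance = 2e-3)
  set.seed(8)
  sep <- cbind(rnorm(1000, 0, 1), rnorm(1000, 5, 1))
  expect_gt(rhat(sep), 1.1)
  expect_error(rhat(matrix(x, ncol = 1)), "at least 2 chains")
  expect_error(rhat(list(1:3, 1:4)), "equal lengths")
})

test_that("potential scale reduction matches the hand-computed formula", {
  # chains (1,2,3) and (2,3,4): W = 1, B = 3*var(c(2,3)) = 1.5,
  # varplus = 2/3 + 0.5 -> rhat = sqrt(7/6)
  expect_equal(rhat(cbind(1:3, 2:4)), sqrt(7 / 6), tolerance = 1e-12)
})

test_that("ratio-scale summaries are summaries of exponentiated draws", {
  set.seed(12)
  draws <- matrix(rnorm(2e5, -0.105, 0.01), ncol = 1)
  s <- summarize_effects(draws, treatment = 2L, outcome = 1L)
  # lognormal mean: exp(mu + sigma^2/2) = exp(-0.10495) = 0.900368
  expect_equal(s$table$hr_mean, exp(-0.105 + 0.01^2 / 2), tolerance = 1e-3)
  expect_lt(s$table$hr_mean, exp(s$table$mean) + 1e-3)  # not exp(summary)
  expect_lte(s$table$q2.5, s$table$q97.5)
})

test_that("degenerate draws give unit ratios and flagged correlations", {
  draws <- matrix(0, 100, 4)
  s <- summarize_effects(draws, treatment = c(2L, 2L, 3L, 3L),
                         outcome = c(1L, 2L, 1L, 2L))
  expect_true(all(s$table$hr_mean == 1))
  expect_true(all(s$table$hr_q2.5 == 1 & s$table$hr_q97.5 == 1))
  expect_true(all(s$table$degenerate))
  expect_true(all(is.na(s$correlations[[1]][1, 2])))
  expect_equal(diag(s$correlations[[1]]), c(outcome_1 = 1, outcome_2 = 1))
})

test_that("no-effect symmetry: identical arms give a ratio interval around 1", {
  s <- make_format_study(3L, list(500, 500), n = 1000L, E = 5000,
                         treatments = c(1L, 2L))
  ds <- nma_dataset(list(s), outcome_labels = "event")
  fit <- fit_nma(ds, "shared", control = mcmc_control(seed = 4))
  tab <- fit$effects$table
  expect_lt(abs(tab$mean), 0.05)
  expect_lt(tab$hr_q2.5, 1)
  expect_gt(tab$hr_q97.5, 1)
  expect_true(fit$converged)
})

test_that("identical seeds reproduce a fit exactly", {
  ds <- make_toy_dataset()
  ctl <- mcmc_control(seed = 77, burn_in = 300L, samples = 400L)
  f1 <- fit_nma(ds, "shared", control = ctl)
  f2 <- fit_nma(ds, "shared", control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_equal(f1$effects$table, f2$effects$table)
})

test_that("reference treatment is pinned, not sampled", {
  ds <- make_toy_dataset()
  fit <- fit_nma(ds, "shared",
                 control = mcmc_control(seed = 2, burn_in = 300L,
                                        samples = 400L))
  eff <- fit$summary[fit$summary$kind == "effect", ]
  expect_equal(nrow(eff), (ds$n_treatments - 1) * ds$n_outcomes)
  expect_false(any(eff$treatment == 1L))
})

test_that("posterior agrees with an independent MCMC engine (JAGS)", {
  skip_if_not_installed("rjags")
  set.seed(41)
  ds <- simulate_scenario(scenario_spec(0.2, 0.2))
  fit <- fit_nma(ds, "shared",
                 control = mcmc_control(seed = 6, burn_in = 3000L,
                                        samples = 6000L))
  cm <- sharednma:::compile_model(ds, "shared")
  sp <- cm$spec
  i1 <- which(sp$type == 1)
  i2 <- which(sp$type == 2)
  dat <- list(C1 = length(i1), b1 = sp$b[i1] + 1, t1 = sp$t[i1],
              bt1 = sp$bt[i1], m1 = sp$m[i1], E1 = sp$E[i1], r1 = sp$r[i1],
              C2 = length(i2), b2 = sp$b[i2] + 1, t2 = sp$t[i2],
              bt2 = sp$bt[i2], m2 = sp$m[i2], n2 = sp$n[i2],
              Tb2 = sp$Tbar[i2], r2 = sp$r[i2], NB = sp$n_b)
  ms <- "
  model {
    for (c in 1:C1) {
      eta1[c] <- omega[b1[c]] + h[t1[c], m1[c]] - h[bt1[c], m1[c]]
      mu1[c] <- E1[c] * exp(eta1[c])
      r1[c] ~ dpois(mu1[c])
    }
    for (c in 1:C2) {
      eta2[c] <- omega[b2[c]] + h[t2[c], m2[c]] - h[bt2[c], m2[c]]
      cloglog(p2[c]) <- log(Tb2[c]) + eta2[c]
      r2[c] ~ dbin(p2[c], n2[c])
    }
    for (j in 1:NB) { omega[j] ~ dnorm(0, 0.5) }
    for (m in 1:2) {
      h[1, m] <- 0
      h[2, m] ~ dnorm(0, 0.5)
      h[3, m] ~ dnorm(0, 0.5)
    }
  }"
  jm <- rjags::jags.model(
    textConnection(ms), data = dat, n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 99))
  update(jm, 3000, progress.bar = "none")
  ss <- rjags::coda.samples(jm, "h", n.iter = 6000, progress.bar = "none")
  sm <- summary(ss)
  jags_mean <- sm$statistics[c("h[2,1]", "h[3,1]", "h[2,2]", "h[3,2]"), "Mean"]
  ours <- fit$effects$table$mean
  names(ours) <- sprintf("h[%d,%d]",
                         fit$summary$treatment[fit$summary$kind == "effect"],
                         fit$summary$outcome[fit$summary$kind == "effect"])
  # 3x a conservative combined Monte-Carlo SE for both samplers
  expect_equal(ours[names(jags_mean)], jags_mean, tolerance = 0.05)
})

test_that("simple-model posterior means track the logistic-regression MLE", {
  # with sd-100 priors and sizeable counts the posterior mean of the log OR
  # is close to the frequentist NMA estimate from glm()
  set.seed(90)
  sc <- scenario_spec(0.2, 0.2)
  ds <- simulate_scenario(sc)
  fit <- fit_nma(ds, "simple",
                 control = mcmc_control(seed = 31, burn_in = 2000L,
                                        samples = 5000L))
  df <- as.data.frame(ds)
  df <- df[df$outcome == "outcome_1", ]
  base_by_study <- tapply(df$treatment, df$study_id, function(x) x[1L])
  df$base <- base_by_study[as.character(df$study_id)]
  X <- data.frame(study = factor(df$study_id))
  for (t in 2:3) X[[paste0("d", t)]] <- (df$treatment == t) - (df$base == t)
  mle <- glm(cbind(df$count, df$n - df$count) ~ study + d2 + d3 - 1,
             family = binomial(), data = X)
  eff <- fit$effects$table
  ours <- eff$mean[fit$summary$outcome[fit$summary$kind == "effect"] == 1]
  expect_equal(ours, unname(coef(mle)[c("d2", "d3")]), tolerance = 0.06)
})
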