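# Frozen expected values below were computed from the direct factorial-form
# pmf expressions (log p = r log mu - mu - log r! etc.), independently of the
# package's likelihood code.

test_that("format-1 likelihood matches the direct Poisson-multinomial pmf", {
  # one informative arm: second arm with zero counts contributes -E*sum(lam)
  s <- study_record("one_arm", 1L, list(
    arm_record(1L, 100L, person_years = 100, counts = c(1, 2)),
    arm_record(2L, 100L, person_years = 100, counts = c(0, 0))))
  lam <- rbind(c(0.01, 0.02), c(0.01, 0.02))
  # arm 1: log Pois(3; 3) + log Mult((1,2); 3, (1/3,2/3)) = -2.30685281944005
  # arm 2: -100 * 0.03 = -3
  expect_equal(loglik_format1(s, lam), -2.30685281944005 - 3, tolerance = 1e-12)
})

test_that("zero-count format-1 arm reduces to the Poisson zero term", {
  s <- make_format_study(1L, list(c(0, 0), c(0, 0)), E = 100)
  lam <- rbind(c(0.013, 0.007), c(0.013, 0.007))
  expect_equal(loglik_format1(s, lam), 2 * (-100 * 0.02), tolerance = 1e-12)
})

test_that("format-1 equals the independent-Poisson factorization identically", {
  # multinomial-Poisson factorization: Pois(R; E*sum(lam)) * Mult(r; R, lam/sum)
  # == prod_m Pois(r_m; E*lam_m), including constants, for every (r, lam, E)
  set.seed(71)
  for (rep in 1:25) {
    counts <- lapply(1:2, function(k) rpois(3, c(2, 5, 1)))
    E <- runif(1, 50, 500)
    s1 <- make_format_study(1L, counts, n = 1000L, E = E)
    s3 <- make_format_study(3L, counts, n = 1000L, E = E)
    lam <- matrix(rexp(6, 30), 2, 3, byrow = TRUE)
    expect_equal(loglik_format1(s1, lam), loglik_format3(s3, lam),
                 tolerance = 1e-10)
  }
})

test_that("format-2 likelihood: cloglog binomial cells and Poisson mortality", {
  # all survivors: r = 0, n = 100, lam = 0.1, Tbar = 1 -> 100*log(exp(-0.1))
  s <- study_record("f2", 2L, list(
    arm_record(1L, 100L, person_years = 100, counts = c(0, NA)),
    arm_record(2L, 100L, person_years = 100, counts = c(0, NA))))
  lam <- rbind(c(0.1, NA), c(0.1, NA))
  expect_equal(loglik_format2(s, lam), -20, tolerance = 1e-12)
  # cell probability under the cloglog link: p = 1 - exp(-0.1)
  s2 <- study_record("f2b", 2L, list(
    arm_record(1L, 100L, person_years = 100, counts = c(10, NA)),
    arm_record(2L, 100L, person_years = 100, counts = c(0, NA))))
  p <- 1 - exp(-0.1)
  expect_equal(loglik_format2(s2, lam),
               dbinom(10, 100, p, log = TRUE) - 10, tolerance = 1e-12)
  # mortality cell is Poisson on person-years: log Pois(4; 100 * 0.0366);
  # the study reports only the mortality outcome
  sm <- study_record("f2m", 2L, list(
    arm_record(1L, 100L, person_years = 100, counts = c(NA, 4)),
    arm_record(2L, 100L, person_years = 100, counts = c(NA, 0))))
  lamm <- rbind(c(NA, 0.0366), c(NA, 0.0366))
  ll <- loglik_format2(sm, lamm, mortality_outcome = 2L)
  # frozen: 4*log(3.66) - 3.66 - log(24) = -1.64820124069485
  expect_equal(ll - dpois(0, 100 * 0.0366, log = TRUE),
               -1.64820124069485, tolerance = 1e-10)
})

test_that("format-2 rejects patients-with-event counts above n", {
  s <- study_record("f2", 2L, list(
    arm_record(1L, 100L, person_years = 100, counts = 101),
    arm_record(2L, 100L, person_years = 100, counts = 1)))
  expect_error(loglik_format2(s, rbind(0.1, 0.1)), "r = 101 > n = 100")
})

test_that("format-3 likelihood is the product of Poisson pmfs", {
  s <- make_format_study(3L, list(c(3, 0), c(0, 0)), E = 100)
  lam <- rbind(c(0.03, 0.01), c(0.03, 0.01))
  # frozen: log(3^3 e^-3 / 3!) = -1.49592260322373
  expect_equal(loglik_format3(s, lam),
               -1.49592260322373 - 1 - 4, tolerance = 1e-10)
  # parameterization invariance: doubling E and halving lam is a no-op
  s2 <- make_format_study(3L, list(c(3, 0), c(0, 0)), E = 200)
  expect_equal(loglik_format3(s2, lam / 2), loglik_format3(s, lam),
               tolerance = 1e-12)
})

test_that("linear predictor implements the consistency equations", {
  params <- model_params(
    baselines = matrix(c(-2, -1), 1, 2),
    effects = rbind(c(0, 0), c(-0.25, -0.25), c(0.25, 0.25)))
  expect_equal(linear_predictor(params, 1, 2, 1, 1), -2.25)
  # arm on the trial's own baseline treatment: effects cancel exactly
  expect_equal(linear_predictor(params, 1, 3, 1, 3), -2)
  # trial comparing 3 vs 2 without a reference arm (consistency equation)
  params2 <- model_params(
    baselines = matrix(-1, 1, 1),
    effects = rbind(0, -0.25, 0.25))
  expect_equal(linear_predictor(params2, 1, 3, 1, 2), -1 + 0.25 - (-0.25))
  expect_error(linear_predictor(params2, 1, 9, 1, 2), "unknown treatment")
})

test_that("simple model is binomial-logit and surfaces count > n", {
  s <- study_record("s", 2L, list(
    arm_record(1L, 100L, person_years = 100, counts = 50),
    arm_record(2L, 100L, person_years = 100, counts = 50)))
  ds <- nma_dataset(list(s), outcome_labels = "x")
  params <- model_params(matrix(0), rbind(0, 0))
  expect_equal(loglik_simple(ds, params),
               2 * dbinom(50, 100, 0.5, log = TRUE), tolerance = 1e-12)
  s_bad <- study_record("s", 3L, list(
    arm_record(1L, 100L, person_years = 100, counts = 120),
    arm_record(2L, 100L, person_years = 100, counts = 50)))
  ds_bad <- nma_dataset(list(s_bad), outcome_labels = "x")
  expect_error(loglik_simple(ds_bad, params), "r = 120 > n = 100")
})

test_that("priors are precision-parameterized normals excluding the reference", {
  p <- prior_spec(0.5, 0.5)
  expect_equal(1 / sqrt(p$baseline_precision), sqrt(2), tolerance = 1e-12)
  expect_equal(1 / sqrt(0.05), 4.47213595499958, tolerance = 1e-12)
  expect_equal(1 / sqrt(1e-4), 100)
  params <- model_params(matrix(c(1.5, NA), 1, 2),
                         rbind(c(0, 0), c(0.3, -0.2)))
  expect_equal(
    log_prior(params, p),
    dnorm(1.5, 0, sqrt(2), log = TRUE) +
      dnorm(0.3, 0, sqrt(2), log = TRUE) +
      dnorm(-0.2, 0, sqrt(2), log = TRUE),
    tolerance = 1e-12)
  # the pinned reference row contributes nothing: same prior as above
  expect_error(model_params(matrix(0), rbind(1, 0)), "reference constraint")
})

test_that("compiled C++ log-posterior equals the R likelihood plus prior", {
  set.seed(99)
  for (ds in list(make_toy_dataset(), {
    set.seed(5); simulate_scenario(scenario_spec(0.2, 0.3))
  })) {
    for (model in c("shared", "simple")) {
      cm <- sharednma:::compile_model(ds, model)
      np <- nrow(cm$param_info)
      prior <- if (model == "shared") prior_spec(0.5, 0.5) else
        prior_spec(1e-4, 1e-4)
      pp <- c(rep(prior$baseline_precision, cm$spec$n_b),
              rep(prior$effect_precision, np - cm$spec$n_b))
      for (rep in 1:5) {
        th <- rnorm(np, -1, 0.4)
        bl <- matrix(NA_real_, length(ds$studies), ds$n_outcomes)
        bl[!is.na(cm$b_idx)] <- th[cm$b_idx[!is.na(cm$b_idx)]]
        eff <- rbind(rep(0, ds$n_outcomes),
                     matrix(th[(cm$spec$n_b + 1):np], ncol = ds$n_outcomes))
        pars <- model_params(bl, eff)
        r_side <- if (model == "shared") loglik_shared(ds, pars) else
          loglik_simple(ds, pars)
        expect_equal(sharednma:::logpost_cells(cm$spec, pp, th),
                     r_side + log_prior(pars, prior), tolerance = 1e-8)
      }
    }
  }
})

test_that("log-densities are finite for positive hazards and valid counts", {
  set.seed(3)
  ds <- simulate_scenario(scenario_spec(0.1, 0.1))
  for (rep in 1:10) {
    pars <- rand_params(ds)
    expect_true(is.finite(loglik_shared(ds, pars)))
  }
})
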