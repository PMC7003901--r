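#' Conditional-kernel log ratio between first-event and total-count models
#'
#' The composition of first events carries information only about relative
#' hazards: conditional on the total count \eqn{R}, the first-event
#' (multinomial) kernel \eqn{\prod_m (\lambda_m/\sum_l \lambda_l)^{r_m}}
#' differs from the independent-Poisson total-count kernel
#' \eqn{\prod_m \lambda_m^{r_m}} by exactly
#' \eqn{(1/\sum_l \lambda_l)^{R}}. This function returns that log ratio,
#' \eqn{-R \log \sum_m \lambda_m}, which vanishes when \eqn{R = 0} and is the
#' hazard-dependent discrepancy that shrinks as events become rare. (The
#' *unconditional* first-event likelihood, which also models \eqn{R}, is
#' identical to the total-count Poisson likelihood by the
#' multinomial-Poisson factorization; the test suite asserts both facts.)
#'
#' @param counts nonnegative integer event counts per outcome.
#' @param hazards positive hazards per outcome.
#' @return \eqn{-R \log(\sum_m \lambda_m)} with \eqn{R = \sum_m r_m}.
#' @export
kernel_log_ratio_f1_f3 <- function(counts, hazards) {
  stopifnot(all(hazards > 0), all(counts >= 0))
  R <- sum(counts)
  if (R == 0) return(0)
  -R * log(sum(hazards))
}

#' Total variation distance between the binomial and its Poisson limit
#'
#' Exact (exhaustively summed) total variation distance between
#' \eqn{\mathrm{Bin}(n, 1 - e^{-\lambda \bar T})} and
#' \eqn{\mathrm{Poisson}(n \lambda \bar T)} — the law-of-rare-events
#' approximation that makes patients-with-event counts and total-event counts
#' interchangeable when events are rare.
#'
#' @param n number of patients.
#' @param hazard event hazard per person-year.
#' @param followup mean follow-up \eqn{\bar T} in years.
#' @return Total variation distance in \[0, 1\].
#' @export
binom_poisson_tv <- function(n, hazard, followup = 1) {
  stopifnot(n >= 1, hazard >= 0)
  if (hazard == 0) return(0)
  p <- -expm1(-hazard * followup)
  mu <- n * hazard * followup
  x <- 0:n
  0.5 * (sum(abs(stats::dbinom(x, n, p) - stats::dpois(x, mu))) +
           stats::ppois(n, mu, lower.tail = FALSE))
}

#' Odds-ratio versus hazard-ratio divergence across event rates
#'
#' For each target average hazard rate, the two arms' hazards are placed
#' symmetrically around the target ((\eqn{\lambda_0 + \lambda_1})/2 = rate
#' with \eqn{\lambda_1/\lambda_0 = e^h}, the same calibration the simulation
#' study uses), converted to per-period event probabilities
#' \eqn{p_i = 1 - e^{-\lambda_i \bar T}}, and the implied odds ratio
#' \eqn{[p_1/(1-p_1)]/[p_0/(1-p_0)]} is compared with the true hazard ratio
#' \eqn{e^h}. Relative divergence is measured on the log scale,
#' \eqn{(\log \mathrm{OR} - h)/h}, the scale on which treatment effects and
#' their bias/coverage are defined; this makes the divergence exactly
#' antisymmetric under \eqn{h \to -h}. The rate at which divergence becomes
#' material is an emergent output, not a constant of the package.
#'
#' @param rate_grid vector of average hazard rates in (0, 1).
#' @param effect true log hazard ratio \eqn{h} (nonzero for a meaningful
#'   relative divergence).
#' @param followup follow-up \eqn{\bar T} in years.
#' @return data.frame with columns `rate`, `hr`, `p0`, `p1`, `or`,
#'   `log_divergence` (signed relative log-scale divergence) and
#'   `abs_divergence`.
#' @export
or_hr_divergence <- function(rate_grid, effect, followup = 1) {
  stopifnot(all(rate_grid > 0), all(rate_grid < 1))
  out <- lapply(rate_grid, function(rate) {
    lam0 <- 2 * rate / (1 + exp(effect))
    lam1 <- lam0 * exp(effect)
    p0 <- -expm1(-lam0 * followup)
    p1 <- -expm1(-lam1 * followup)
    or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    ld <- if (effect == 0) 0 else (log(or) - effect) / effect
    data.frame(rate = rate, hr = exp(effect), p0 = p0, p1 = p1, or = or,
               log_divergence = ld, abs_divergence = abs(ld))
  })
  do.call(rbind, out)
}
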