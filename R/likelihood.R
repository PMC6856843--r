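#' Probability of a positive test at a transformed threshold
#'
#' Under the model, transformed test results in a group follow a logistic
#' distribution with location `mu` and scale `sigma`, so the probability of
#' a result exceeding a threshold with transformed value `gC` is
#' \deqn{\mathrm{logit}(pr) = (\mu - g(C)) / \sigma.}
#'
#' @param mu location of the transformed test-result distribution.
#' @param sigma positive scale of the logistic distribution.
#' @param gC transformed threshold value(s).
#' @return probability (vector), strictly decreasing in `gC`.
#' @export
positive_rate <- function(mu, sigma, gC) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  stats::plogis((mu - gC) / sigma)
}

# clip probabilities away from 0/1 before taking logs
clip_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Factorised multinomial log-likelihood of a study-group's counts
#'
#' The counts above successive thresholds are modelled as a chain of
#' conditional binomials: `x_1 ~ Bin(N, pr_1)` and
#' `x_t | x_{t-1} ~ Bin(x_{t-1}, pr_t / pr_{t-1})`, where `pr_t` is the
#' positive-test probability at threshold `t` from [positive_rate()].
#' Because the `pr_t` are automatically decreasing in the threshold, every
#' conditional probability lies in (0, 1) without explicit ordering
#' constraints. All binomial coefficients are included, so the value agrees
#' exactly with the direct multinomial log-pmf ([loglik_multinomial()]).
#'
#' @param N group size.
#' @param counts_above non-increasing counts above each threshold.
#' @param thresholds strictly increasing thresholds (positive).
#' @param mu,sigma logistic location/scale of the transformed results.
#' @param lambda Box-Cox parameter of the threshold transform.
#' @return log-likelihood (finite for all valid inputs).
#' @export
loglik_factorized <- function(N, counts_above, thresholds, mu, sigma, lambda) {
  cc <- conditional_counts(N, counts_above)
  pr <- clip_p(positive_rate(mu, sigma, boxcox(thresholds, lambda)))
  p_cond <- clip_p(pr / c(1, pr[-length(pr)]))
  sum(stats::dbinom(cc$successes, cc$trials, p_cond, log = TRUE))
}

#' Direct multinomial log-likelihood (reference oracle)
#'
#' Computes the same likelihood as [loglik_factorized()] via the multinomial
#' distribution of the counts over the `T + 1` threshold-delimited
#' categories, with cell probabilities
#' `(1 - pr_1, pr_1 - pr_2, ..., pr_T)` and cell counts
#' `(N - x_1, x_1 - x_2, ..., x_T)`. Kept as an independent route for
#' validating the factorisation; the model itself always uses the
#' factorised form.
#'
#' @inheritParams loglik_factorized
#' @return log-likelihood.
#' @export
loglik_multinomial <- function(N, counts_above, thresholds, mu, sigma, lambda) {
  pr <- clip_p(positive_rate(mu, sigma, boxcox(thresholds, lambda)))
  cell_p <- c(1, pr) - c(pr, 0)
  cell_x <- c(N, counts_above) - c(counts_above, 0)
  stats::dmultinom(cell_x, prob = cell_p, log = TRUE)
}

# residual deviance contribution of one set of binomial cells
deviance_cells <- function(x, trials, phat) {
  if (any(phat <= 0) || any(phat >= 1))
    stop("fitted probabilities must lie strictly in (0, 1)", call. = FALSE)
  m <- trials * phat
  t1 <- ifelse(x > 0, x * log(x / m), 0)
  t2 <- ifelse(trials - x > 0, (trials - x) * log((trials - x) / (trials - m)), 0)
  2 * sum(ifelse(trials > 0, t1 + t2, 0))
}

#' Residual deviance of fitted positive-test rates
#'
#' Deviance of the observed counts against fitted rates, accumulated over
#' the same conditional-binomial terms the likelihood factorises into:
#' \deqn{2 \sum \left[ x \log\frac{x}{n\hat p} +
#'   (n - x) \log\frac{n - x}{n - n\hat p} \right],}
#' with the usual `0 log 0 = 0` conventions. Zero at the saturated fit.
#' This is the quantity whose posterior mean enters the DIC.
#'
#' @param data a [dta_data] object.
#' @param fitted_rates data frame aligned with `data$counts` (same
#'   study/group/threshold order) with a column `rate` holding the fitted
#'   unconditional positive-test probability at each threshold.
#' @return non-negative deviance.
#' @export
residual_deviance <- function(data, fitted_rates) {
  ot <- obs_table(data)
  if (nrow(fitted_rates) != nrow(ot))
    stop("fitted_rates must have one row per observation", call. = FALSE)
  pr <- fitted_rates$rate
  if (any(pr <= 0) || any(pr >= 1))
    stop("fitted rates must lie strictly in (0, 1)", call. = FALSE)
  p_cond <- ifelse(ot$first == 1, pr, pr / pr[ot$prev])
  deviance_cells(ot$count_above, ot$trials, clip_p(p_cond))
}
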