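# Default grid: log-spaced points spanning the observed threshold range.
default_grid <- function(data, n = 200) {
  rng <- range(data$counts$threshold)
  g <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
  g[1] <- rng[1]; g[n] <- rng[2]  # pin endpoints against log/exp drift
  g
}

# Draws x grid matrices of summary logit-fpr / logit-tpr: the summary
# formulas evaluate the exceedance link at the means of the four sets of
# random effects, per posterior draw.
summary_rate_draws <- function(fit, grid) {
  dr <- fit$draws
  if (fit$transform$mode == "estimated") {
    lam <- dr[, "lambda"]
    lc <- log(grid)
    GC <- (exp(outer(lam, lc)) - 1) / lam
  } else {
    GC <- matrix(boxcox(grid, fit$transform$lambda), nrow(dr), length(grid),
                 byrow = TRUE)
  }
  list(fpr = stats::plogis((dr[, "m_mu[1]"] - GC) / exp(dr[, "m_sigma[1]"])),
       tpr = stats::plogis((dr[, "m_mu[2]"] - GC) / exp(dr[, "m_sigma[2]"])))
}

#' Summary accuracy curve across thresholds
#'
#' For each posterior draw, evaluates the summary false and true positive
#' rates at every grid threshold from the population means:
#' \deqn{\mathrm{logit}\, fpr(C) = (m_{\mu 1} - g(C)) / \exp(m_{\sigma 1}),
#'   \qquad \mathrm{logit}\, tpr(C) = (m_{\mu 2} - g(C)) / \exp(m_{\sigma 2}),}
#' then summarises across draws: the headline point estimate is the
#' posterior median of the curve (transformation-equivariant), with the
#' curve at the posterior-median parameters also returned for reference,
#' and central 95% credible intervals.
#'
#' The default grid is 200 log-spaced points spanning the observed
#' threshold range. Grids extending beyond the data are allowed but
#' flagged (attribute `extrapolated` and a warning): estimates at extreme
#' thresholds with little or no data should be interpreted cautiously.
#'
#' @param fit a [fit_dta()] (or [as_dta_fit()]) result.
#' @param grid increasing vector of thresholds; default spans the observed
#'   range.
#' @param level credible level for the intervals.
#' @return data frame of class `"dta_curve"` with columns `threshold`,
#'   `fpr`, `fpr_lo`, `fpr_hi`, `tpr`, `tpr_lo`, `tpr_hi`,
#'   `fpr_at_median`, `tpr_at_median`.
#' @export
summary_curve <- function(fit, grid = NULL, level = 0.95) {
  if (is.null(grid)) {
    if (is.null(fit$data))
      stop("no grid given and the fit carries no dataset", call. = FALSE)
    grid <- default_grid(fit$data)
  }
  if (any(grid <= 0)) stop("grid thresholds must be positive", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  extrap <- FALSE
  if (!is.null(fit$data)) {
    rng <- range(fit$data$counts$threshold)
    extrap <- min(grid) < rng[1] * (1 - 1e-10) ||
      max(grid) > rng[2] * (1 + 1e-10)
    if (extrap)
      warning("grid extends beyond the observed threshold range; ",
              "extrapolated estimates are flagged", call. = FALSE)
  }
  sr <- summary_rate_draws(fit, grid)
  a <- (1 - level) / 2
  q <- function(M, p) apply(M, 2, stats::quantile, p)
  med <- apply(fit$draws[, c("m_mu[1]", "m_mu[2]", "m_sigma[1]",
                             "m_sigma[2]"), drop = FALSE], 2, stats::median)
  lam_med <- if (fit$transform$mode == "estimated")
    stats::median(fit$draws[, "lambda"]) else fit$transform$lambda
  gmed <- boxcox(grid, lam_med)
  out <- data.frame(
    threshold = grid,
    fpr = q(sr$fpr, 0.5), fpr_lo = q(sr$fpr, a), fpr_hi = q(sr$fpr, 1 - a),
    tpr = q(sr$tpr, 0.5), tpr_lo = q(sr$tpr, a), tpr_hi = q(sr$tpr, 1 - a),
    fpr_at_median = stats::plogis((med["m_mu[1]"] - gmed) / exp(med["m_sigma[1]"])),
    tpr_at_median = stats::plogis((med["m_mu[2]"] - gmed) / exp(med["m_sigma[2]"])))
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "extrapolated") <- extrap
  class(out) <- c("dta_curve", "data.frame")
  out
}

# One new-study draw of (mu1, mu2, logsigma1, logsigma2) per posterior
# draw, respecting the fitted between-study structure.
predictive_effect_draws <- function(fit) {
  dr <- fit$draws
  nd <- nrow(dr)
  m <- dr[, c("m_mu[1]", "m_mu[2]", "m_sigma[1]", "m_sigma[2]"), drop = FALSE]
  tau <- dr[, c("tau_mu[1]", "tau_mu[2]", "tau_sigma[1]", "tau_sigma[2]"),
            drop = FALSE]
  out <- matrix(0, nd, 4)
  if (fit$structure == "independence") {
    for (k in 1:4) out[, k] <- stats::rnorm(nd, m[, k], tau[, k])
  } else if (fit$structure == "structured") {
    rm <- dr[, "rho_mu"]; rs <- dr[, "rho_musig"]
    out[, 1] <- stats::rnorm(nd, m[, 1], tau[, 1])
    out[, 2] <- stats::rnorm(nd,
      m[, 2] + rm * (tau[, 2] / tau[, 1]) * (out[, 1] - m[, 1]),
      sqrt(1 - rm^2) * tau[, 2])
    out[, 3] <- stats::rnorm(nd,
      m[, 3] + rs * (tau[, 3] / tau[, 1]) * (out[, 1] - m[, 1]),
      sqrt(1 - rs^2) * tau[, 3])
    out[, 4] <- stats::rnorm(nd,
      m[, 4] + rs * (tau[, 4] / tau[, 2]) * (out[, 2] - m[, 2]),
      sqrt(1 - rs^2) * tau[, 4])
  } else {
    B <- fit$draws[, paste0("b[", 1:6, "]"), drop = FALSE]
    PS <- fit$draws[, paste0("psi[", 1:4, "]"), drop = FALSE]
    for (r in seq_len(nd)) {
      S <- pn_sigma(B[r, ], PS[r, ])
      out[r, ] <- m[r, ] + drop(stats::rnorm(4) %*% chol(S))
    }
  }
  out
}

#' Prediction intervals for the accuracy of a new study
#'
#' For each posterior draw, samples one new study's random effects from
#' the fitted between-study distribution (respecting the correlation
#' structure) and evaluates its false/true positive rates on the grid.
#' Pointwise percentiles of those rates form the prediction bands, which
#' incorporate between-study heterogeneity on top of estimation
#' uncertainty and are therefore at least as wide as the credible
#' intervals (equal when all between-study SDs are zero).
#'
#' @inheritParams summary_curve
#' @param seed integer seed for the predictive draws.
#' @return data frame of class `"dta_curve"`: the [summary_curve()]
#'   columns plus `fpr_pi_lo`, `fpr_pi_hi`, `tpr_pi_lo`, `tpr_pi_hi`.
#' @export
prediction_curve <- function(fit, grid = NULL, level = 0.95, seed = 1) {
  sc <- suppressWarnings(summary_curve(fit, grid, level))
  grid <- sc$threshold
  set.seed(seed)
  eff <- predictive_effect_draws(fit)
  if (fit$transform$mode == "estimated") {
    lam <- fit$draws[, "lambda"]
    GC <- (exp(outer(lam, log(grid))) - 1) / lam
  } else {
    GC <- matrix(boxcox(grid, fit$transform$lambda), nrow(eff), length(grid),
                 byrow = TRUE)
  }
  fpr_new <- stats::plogis((eff[, 1] - GC) / exp(eff[, 3]))
  tpr_new <- stats::plogis((eff[, 2] - GC) / exp(eff[, 4]))
  a <- (1 - level) / 2
  sc$fpr_pi_lo <- apply(fpr_new, 2, stats::quantile, a)
  sc$fpr_pi_hi <- apply(fpr_new, 2, stats::quantile, 1 - a)
  sc$tpr_pi_lo <- apply(tpr_new, 2, stats::quantile, a)
  sc$tpr_pi_hi <- apply(tpr_new, 2, stats::quantile, 1 - a)
  sc
}

#' Summary ROC curve
#'
#' The parametric summary ROC curve traced by the pair of summary rate
#' formulas as the threshold runs along the grid: each grid point maps to
#' `(fpr(C), tpr(C))` at the posterior medians. Both coordinates decrease
#' with increasing threshold.
#'
#' @inheritParams summary_curve
#' @return data frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   threshold.
#' @export
sroc_curve <- function(fit, grid = NULL) {
  sc <- suppressWarnings(summary_curve(fit, grid))
  data.frame(threshold = sc$threshold, fpr = sc$fpr, tpr = sc$tpr)
}

#' Optimal threshold by the (weighted) Youden index
#'
#' Maximises the weighted Youden index over the curve's grid:
#' \deqn{J_w = 2\,[w \cdot tpr + (1 - w)(1 - fpr)] - 1,}
#' which at `sens_weight = 0.5` reduces to the classical
#' `J = sensitivity + specificity - 1 = tpr - fpr`. Weights above 0.5
#' favour sensitivity (rule-out use) and move the optimum to lower
#' thresholds. Ties resolve to the smallest threshold.
#'
#' @param curve a [summary_curve()] result with at least 100 grid points.
#' @param sens_weight weight on sensitivity, in (0, 1).
#' @return list with `threshold`, `sens`, `spec` and `youden` (the
#'   achieved weighted index).
#' @export
youden_optimal <- function(curve, sens_weight = 0.5) {
  stopifnot(inherits(curve, "data.frame"),
            all(c("threshold", "fpr", "tpr") %in% names(curve)))
  if (nrow(curve) < 100)
    warning("fewer than 100 grid points; the optimum may be coarse",
            call. = FALSE)
  w <- sens_weight
  stopifnot(w > 0, w < 1)
  J <- 2 * (w * curve$tpr + (1 - w) * (1 - curve$fpr)) - 1
  i <- which(J >= max(J) - 1e-12)[1]  # ties -> smallest threshold
  list(threshold = curve$threshold[i], sens = curve$tpr[i],
       spec = 1 - curve$fpr[i], youden = J[i])
}

#' Multiplicative covariate effect on the mean test result
#'
#' When the threshold scale is log-transformed (fixed Box-Cox parameter
#' 0), a meta-regression coefficient `alpha` on a location parameter has a
#' ratio interpretation: a covariate change of `delta` multiplies the mean
#' test result in that group by `exp(delta * alpha)`. Returns the
#' posterior median and credible interval of that ratio. For any other
#' transform the ratio interpretation does not hold and an error is
#' raised.
#'
#' @param fit a [fit_dta()] result with covariates on `mu1` and/or `mu2`.
#' @param covariate covariate name.
#' @param delta covariate change of interest (e.g. 5 years).
#' @param group `"disease_free"` or `"diseased"`.
#' @param level credible level.
#' @return list with `ratio`, `cri` (length 2) and the coefficient draws'
#'   summary.
#' @export
covariate_ratio <- function(fit, covariate, delta,
                            group = c("disease_free", "diseased"),
                            level = 0.95) {
  group <- match.arg(group)
  if (!(fit$transform$mode == "fixed" && fit$transform$lambda == 0))
    stop("ratio interpretation requires the log transform ",
         "(fixed Box-Cox parameter 0)", call. = FALSE)
  tg <- if (group == "disease_free") "mu1" else "mu2"
  col <- sprintf("alpha_%s[%s]", tg, covariate)
  if (!col %in% colnames(fit$draws))
    stop("no fitted coefficient for covariate '", covariate,
         "' on target ", tg, call. = FALSE)
  ratio <- exp(delta * fit$draws[, col])
  a <- (1 - level) / 2
  list(ratio = stats::median(ratio),
       cri = unname(stats::quantile(ratio, c(a, 1 - a))),
       alpha_median = stats::median(fit$draws[, col]))
}

#' Plot an accuracy curve
#'
#' Two-panel base-graphics display: true and false positive rate against
#' threshold (log axis), with credible bands and, when present,
#' prediction bands.
#'
#' @param x a `"dta_curve"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dta_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  has_pi <- "tpr_pi_lo" %in% names(x)
  panel <- function(rate, lo, hi, pilo, pihi, lab) {
    graphics::plot(x$threshold, rate, type = "n", log = "x", ylim = c(0, 1),
                   xlab = "threshold", ylab = lab, ...)
    if (has_pi)
      graphics::polygon(c(x$threshold, rev(x$threshold)), c(pilo, rev(pihi)),
                        col = "grey90", border = NA)
    graphics::polygon(c(x$threshold, rev(x$threshold)), c(lo, rev(hi)),
                      col = "grey75", border = NA)
    graphics::lines(x$threshold, rate, lwd = 2)
  }
  panel(x$tpr, x$tpr_lo, x$tpr_hi, x$tpr_pi_lo, x$tpr_pi_hi, "tpr (sensitivity)")
  panel(x$fpr, x$fpr_lo, x$fpr_hi, x$fpr_pi_lo, x$fpr_pi_hi, "fpr (1 - specificity)")
  invisible(x)
}
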