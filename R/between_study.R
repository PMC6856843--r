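#' Hyperparameters of the between-study model
#'
#' Collects the population-level parameters: means of the study-specific
#' locations (`m_mu`, length 2: disease-free, diseased) and of the
#' log-scales (`m_sigma`), the corresponding between-study standard
#' deviations (`tau_mu`, `tau_sigma`), the correlation parameters required
#' by the chosen structure, optional meta-regression coefficients, and the
#' Box-Cox parameter.
#'
#' Correlations by structure:
#' * `"independence"`: none.
#' * `"structured"`: `rho_mu` (between the two locations) and `rho_musig`
#'   (between each location and its own log-scale; all other correlations
#'   are induced, never free).
#' * `"full"`: all six pairwise correlations of
#'   `(mu_1, mu_2, log sigma_1, log sigma_2)`, named `rho_mu`, `rho_mu1s1`,
#'   `rho_mu1s2`, `rho_mu2s1`, `rho_mu2s2`, `rho_s`.
#'
#' @param m_mu,m_sigma numeric length 2.
#' @param tau_mu,tau_sigma non-negative numeric length 2.
#' @param rho named list of correlations (see above), each in (-1, 1).
#' @param alpha optional named list of meta-regression coefficient vectors
#'   for targets `mu1`, `mu2`, `sigma1`, `sigma2`; each element is a named
#'   numeric vector (names = covariate names).
#' @param lambda Box-Cox parameter.
#' @return list of class `"dta_hyperparams"`.
#' @export
hyperparams <- function(m_mu, m_sigma, tau_mu, tau_sigma,
                        rho = list(), alpha = NULL, lambda = 0) {
  stopifnot(length(m_mu) == 2, length(m_sigma) == 2,
            length(tau_mu) == 2, length(tau_sigma) == 2,
            all(tau_mu >= 0), all(tau_sigma >= 0))
  if (length(rho) && any(abs(unlist(rho)) >= 1))
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  structure(list(m_mu = as.numeric(m_mu), m_sigma = as.numeric(m_sigma),
                 tau_mu = as.numeric(tau_mu), tau_sigma = as.numeric(tau_sigma),
                 rho = rho, alpha = alpha, lambda = lambda),
            class = "dta_hyperparams")
}

rho_get <- function(hp, name) {
  v <- hp$rho[[name]]
  if (is.null(v)) 0 else v
}

#' Between-study covariance matrix of (mu1, mu2, log sigma1, log sigma2)
#'
#' Builds the 4x4 covariance implied by the hyperparameters under the given
#' structure. For `"full"` the six correlations are free and the matrix
#' must be positive definite (an error is raised otherwise, never a silent
#' repair). For `"structured"` the matrix is the one implied by the
#' conditional decomposition: `rho_mu` and `rho_musig` are free, every
#' other correlation is induced through them. For `"independence"` the
#' matrix is diagonal.
#'
#' @param hp a [hyperparams] object.
#' @param structure `"full"`, `"structured"` or `"independence"`.
#' @return 4x4 covariance matrix, rows/cols ordered
#'   `(mu1, mu2, log sigma1, log sigma2)`.
#' @export
between_study_sigma <- function(hp,
    structure = c("independence", "structured", "full")) {
  structure <- match.arg(structure)
  tt <- c(hp$tau_mu, hp$tau_sigma)
  R <- diag(4)
  if (structure == "full") {
    R[1, 2] <- rho_get(hp, "rho_mu")
    R[1, 3] <- rho_get(hp, "rho_mu1s1")
    R[1, 4] <- rho_get(hp, "rho_mu1s2")
    R[2, 3] <- rho_get(hp, "rho_mu2s1")
    R[2, 4] <- rho_get(hp, "rho_mu2s2")
    R[3, 4] <- rho_get(hp, "rho_s")
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(abs(ev)))
      stop("full-structure correlation matrix is not positive definite",
           call. = FALSE)
  } else if (structure == "structured") {
    rm <- rho_get(hp, "rho_mu"); rs <- rho_get(hp, "rho_musig")
    R[1, 2] <- rm
    R[1, 3] <- rs            # mu1 with log sigma1
    R[2, 4] <- rs            # mu2 with log sigma2
    R[1, 4] <- rm * rs       # induced: mu1 with log sigma2
    R[2, 3] <- rm * rs       # induced: mu2 with log sigma1
    R[3, 4] <- rm * rs^2     # induced: log sigma1 with log sigma2
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
  }
  diag(tt) %*% R %*% diag(tt)
}

# Mean vector (mu1, mu2, log sigma1, log sigma2) with covariate offsets.
# z: named numeric vector of this study's covariate values (already
# centered if centering is in use).
ranef_mean <- function(hp, z = NULL) {
  m <- c(hp$m_mu, hp$m_sigma)
  if (!is.null(hp$alpha) && !is.null(z)) {
    tg <- c("mu1", "mu2", "sigma1", "sigma2")
    for (k in seq_along(tg)) {
      a <- hp$alpha[[tg[k]]]
      if (!is.null(a) && length(a))
        m[k] <- m[k] + sum(a * z[names(a)])
    }
  }
  m
}

#' Log-density of a study's random effects
#'
#' Evaluates the log of the quadrivariate normal density of
#' `(mu_1, mu_2, log sigma_1, log sigma_2)` for one study under the chosen
#' between-study structure, with means optionally shifted by
#' meta-regression terms `alpha' z`. The `"structured"` branch uses the
#' exact conditional decomposition (location 1; location 2 given location
#' 1; each log-scale given its own location); `"full"` uses the dense
#' covariance with a Cholesky factorisation and errors on non-positive-
#' definite correlation matrices.
#'
#' @param effects numeric length 4: `(mu1, mu2, log sigma1, log sigma2)`.
#' @param hp a [hyperparams] object.
#' @param structure between-study structure.
#' @param z optional named covariate vector for this study.
#' @return log-density.
#' @export
ranef_logpdf <- function(effects, hp,
    structure = c("independence", "structured", "full"), z = NULL) {
  structure <- match.arg(structure)
  stopifnot(length(effects) == 4)
  m <- ranef_mean(hp, z)
  if (structure == "independence") {
    sds <- c(hp$tau_mu, hp$tau_sigma)
    return(sum(stats::dnorm(effects, m, sds, log = TRUE)))
  }
  if (structure == "structured") {
    rm <- rho_get(hp, "rho_mu"); rs <- rho_get(hp, "rho_musig")
    tm <- hp$tau_mu; ts <- hp$tau_sigma
    l1 <- stats::dnorm(effects[1], m[1], tm[1], log = TRUE)
    l2 <- stats::dnorm(effects[2],
                       m[2] + rm * (tm[2] / tm[1]) * (effects[1] - m[1]),
                       sqrt(1 - rm^2) * tm[2], log = TRUE)
    l3 <- stats::dnorm(effects[3],
                       m[3] + rs * (ts[1] / tm[1]) * (effects[1] - m[1]),
                       sqrt(1 - rs^2) * ts[1], log = TRUE)
    l4 <- stats::dnorm(effects[4],
                       m[4] + rs * (ts[2] / tm[2]) * (effects[2] - m[2]),
                       sqrt(1 - rs^2) * ts[2], log = TRUE)
    return(l1 + l2 + l3 + l4)
  }
  S <- between_study_sigma(hp, "full")
  L <- chol(S)
  dev <- backsolve(L, effects - m, transpose = TRUE)
  -0.5 * sum(dev^2) - sum(log(diag(L))) - 2 * log(2 * pi)
}

#' Sample study-level random effects
#'
#' Draws `(mu_1, mu_2, log sigma_1, log sigma_2)` for `n` new studies from
#' the between-study distribution. The `"structured"` branch samples
#' through its exact conditional decomposition; `"full"` through the
#' Cholesky factor of the dense covariance; `"independence"` from four
#' independent normals. Used both by the synthetic-data generator and for
#' prediction intervals (accuracy in a new study population).
#'
#' @inheritParams ranef_logpdf
#' @param n number of studies to draw.
#' @param seed optional integer seed.
#' @return `n x 4` matrix with columns `mu1`, `mu2`, `logsigma1`,
#'   `logsigma2`.
#' @export
sample_study_effects <- function(hp,
    structure = c("independence", "structured", "full"),
    n = 1, z = NULL, seed = NULL) {
  structure <- match.arg(structure)
  if (!is.null(seed)) set.seed(seed)
  m <- ranef_mean(hp, z)
  out <- matrix(0, n, 4,
                dimnames = list(NULL, c("mu1", "mu2", "logsigma1", "logsigma2")))
  if (structure == "independence") {
    sds <- c(hp$tau_mu, hp$tau_sigma)
    for (k in 1:4) out[, k] <- stats::rnorm(n, m[k], sds[k])
  } else if (structure == "structured") {
    rm <- rho_get(hp, "rho_mu"); rs <- rho_get(hp, "rho_musig")
    tm <- hp$tau_mu; ts <- hp$tau_sigma
    out[, 1] <- stats::rnorm(n, m[1], tm[1])
    out[, 2] <- stats::rnorm(n, m[2] + rm * (tm[2] / tm[1]) * (out[, 1] - m[1]),
                             sqrt(1 - rm^2) * tm[2])
    out[, 3] <- stats::rnorm(n, m[3] + rs * (ts[1] / tm[1]) * (out[, 1] - m[1]),
                             sqrt(1 - rs^2) * ts[1])
    out[, 4] <- stats::rnorm(n, m[4] + rs * (ts[2] / tm[2]) * (out[, 2] - m[2]),
                             sqrt(1 - rs^2) * ts[2])
  } else {
    S <- between_study_sigma(hp, "full")
    L <- chol(S)
    eps <- matrix(stats::rnorm(4 * n), n, 4)
    out <- sweep(eps %*% L, 2, m, "+")
    colnames(out) <- c("mu1", "mu2", "logsigma1", "logsigma2")
  }
  out
}

#' Prior configuration
#'
#' Defaults follow common weakly-informative practice for this model class:
#' Normal(0, `mean_sd`^2) on all means and meta-regression coefficients
#' (default SD 10), Uniform(0, `tau_upper`) on between-study SDs (default
#' 5), Uniform(-1, 1) on free correlations, and the uniform prior from the
#' transformation spec on an estimated Box-Cox parameter.
#'
#' @param mean_sd prior SD of means and coefficients.
#' @param tau_upper upper bound of the uniform prior on between-study SDs.
#' @return list of class `"dta_priors"`.
#' @export
prior_config <- function(mean_sd = 10, tau_upper = 5) {
  stopifnot(mean_sd > 0, tau_upper > 0)
  structure(list(mean_sd = mean_sd, tau_upper = tau_upper,
                 rho_bounds = c(-1, 1)),
            class = "dta_priors")
}

#' Enumerate the priors active under a model configuration
#'
#' Returns one named entry per free hyperparameter: the four means, four
#' between-study SDs, the correlations required by the structure, one
#' coefficient per covariate per regression target, and the Box-Cox
#' parameter when it is estimated.
#'
#' @param config a [prior_config] object.
#' @param structure between-study structure.
#' @param covariate_targets named list mapping regression targets
#'   (`mu1`, `mu2`, `sigma1`, `sigma2`) to character vectors of covariate
#'   names (as accepted by [fit_dta()]).
#' @param transform a [transform_spec] object.
#' @return named list of prior descriptors
#'   (`list(dist = , pars = )` each).
#' @export
build_prior <- function(config = prior_config(),
    structure = c("independence", "structured", "full"),
    covariate_targets = NULL, transform = transform_spec()) {
  structure <- match.arg(structure)
  pr <- list()
  norm0 <- list(dist = "normal", pars = c(mean = 0, sd = config$mean_sd))
  unif_tau <- list(dist = "uniform", pars = c(low = 0, high = config$tau_upper))
  unif_rho <- list(dist = "uniform", pars = c(low = -1, high = 1))
  for (nm in c("m_mu[1]", "m_mu[2]", "m_sigma[1]", "m_sigma[2]"))
    pr[[nm]] <- norm0
  for (nm in c("tau_mu[1]", "tau_mu[2]", "tau_sigma[1]", "tau_sigma[2]"))
    pr[[nm]] <- unif_tau
  rho_names <- switch(structure,
    independence = character(0),
    structured = c("rho_mu", "rho_musig"),
    full = c("rho_mu", "rho_mu1s1", "rho_mu1s2", "rho_mu2s1", "rho_mu2s2",
             "rho_s"))
  for (nm in rho_names) pr[[nm]] <- unif_rho
  if (!is.null(covariate_targets)) {
    for (tg in names(covariate_targets))
      for (cv in covariate_targets[[tg]])
        pr[[paste0("alpha_", tg, "[", cv, "]")]] <- norm0
  }
  if (transform$mode == "estimated")
    pr[["lambda"]] <- list(dist = "uniform",
                           pars = c(low = transform$prior[1],
                                    high = transform$prior[2]))
  pr
}
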