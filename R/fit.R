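#' Fit the multi-threshold meta-analysis model by MCMC
#'
#' Assembles and samples the hierarchical model: within each study-group,
#' exact multinomial likelihoods of the counts above each threshold via
#' their binomial factorisation; positive-test probabilities linked to the
#' Box-Cox-transformed threshold through a logistic distribution with
#' study-specific location and scale; between-study normal random effects
#' on the two locations and two log-scales under an `"independence"`,
#' `"structured"` or `"full"` correlation structure; optional study-level
#' covariates shifting any of the four random-effect means.
#'
#' Sampling uses JAGS. For the `"full"` structure the dense quadrivariate
#' normal is parameterised through sequential conditional regressions
#' (product-normal form), which is positive definite by construction; the
#' implied between-study SDs and six correlations are derived from the
#' sampled parameters and included in the returned draws under the
#' canonical names (`tau_mu[1]`, ..., `rho_mu`, `rho_mu1s1`, ...).
#'
#' Covariates are mean-centered by default before entering the model, so
#' that the population means retain their interpretation at the average
#' study. Reproducibility: the chain RNGs are seeded deterministically
#' from `seed`.
#'
#' @param data a [dta_data] object.
#' @param structure between-study structure: `"independence"`,
#'   `"structured"` or `"full"`.
#' @param transform a [transform_spec] (fixed or estimated Box-Cox
#'   parameter).
#' @param covariates optional named list mapping regression targets
#'   (`mu1`, `mu2`, `sigma1`, `sigma2`) to character vectors of covariate
#'   column names in `data$covariates`, e.g.
#'   `list(mu1 = "age", mu2 = "age")`.
#' @param priors a [prior_config] object.
#' @param chains number of MCMC chains (at least 2 for convergence
#'   diagnostics).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param iter retained sampling iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed (required).
#' @param center_covariates centre covariates at their mean before use.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `"dta_fit"` with elements `draws` (matrix,
#'   one row per retained draw across chains, canonical column names),
#'   `mcmc` (the underlying `coda::mcmc.list`), `data`, `structure`,
#'   `transform`, `covariates`, `covariate_centers`, `priors`,
#'   `diagnostics` (per-parameter R-hat and effective sample size) and
#'   `dic` (see [compute_dic()]).
#' @export
fit_dta <- function(data, structure = c("independence", "structured", "full"),
                    transform = transform_spec(), covariates = NULL,
                    priors = prior_config(), chains = 4, warmup = 1000,
                    iter = 1000, thin = 1, seed, center_covariates = TRUE,
                    quiet = TRUE) {
  structure <- match.arg(structure)
  stopifnot(inherits(data, "dta_data"), inherits(transform, "dta_transform"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for reproducibility", call. = FALSE)
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  validate_dta(data)
  ot <- obs_table(data)
  sids <- attr(ot, "study_ids")
  nstud <- length(sids)
  lambda_est <- transform$mode == "estimated"
  if (!lambda_est && transform$lambda != 0 && any(data$counts$threshold <= 0))
    stop("non-positive thresholds are incompatible with a Box-Cox transform",
         call. = FALSE)
  if (any(data$counts$threshold <= 0))
    stop("thresholds must be strictly positive", call. = FALSE)

  # per-target covariate design matrices
  cov_info <- resolve_covariates(data, covariates, center_covariates, sids)

  jd <- list(Nobs = nrow(ot), Nstud = nstud, s = ot$study, jg = ot$group,
             x = ot$count_above, trials = ot$trials, first = ot$first,
             prev = ot$prev)
  if (lambda_est) jd$Cth <- ot$threshold else
    jd$gC <- boxcox(ot$threshold, transform$lambda)
  for (k in 1:4) if (cov_info$active_k[k] > 0)
    jd[[paste0("Z", k)]] <- cov_info$Z[[k]]

  code <- jags_model_code(structure, lambda_est, cov_info$active_k, priors,
                          if (lambda_est) transform$prior else NULL)
  monitors <- c("m_mu", "m_sigma", "mu", "logsigma")
  monitors <- c(monitors, switch(structure,
    independence = c("tau_mu", "tau_sigma"),
    structured = c("tau_mu", "tau_sigma", "rho_mu", "rho_musig"),
    full = c("psi", "b")))
  tgs <- c("mu1", "mu2", "sigma1", "sigma2")
  for (k in 1:4) if (cov_info$active_k[k] > 0)
    monitors <- c(monitors, paste0("alpha_", tgs[k]))
  if (lambda_est) monitors <- c(monitors, "lambda")

  # start the location means at the centre of the transformed threshold
  # range: far better conditioned than arbitrary constants when the test
  # scale is large
  lam0 <- if (lambda_est) {
    mid <- mean(transform$prior)
    if (abs(mid) < 1e-6) 0.1 else mid
  } else transform$lambda
  gmid <- stats::median(boxcox(ot$threshold, lam0))
  inits <- lapply(seq_len(chains), function(ch) {
    tau0 <- min(0.5, priors$tau_upper / 2)
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (as.integer(seed) * 97L + ch * 1009L) %% 2147483399L + 1L,
                m_mu = c(gmid, gmid + 1), m_sigma = c(0, 0))
    if (structure %in% c("independence", "structured"))
      ini <- c(ini, list(tau_mu = rep(tau0, 2), tau_sigma = rep(tau0, 2)))
    if (structure == "structured")
      ini <- c(ini, list(rho_mu = 0, rho_musig = 0))
    if (structure == "full")
      ini <- c(ini, list(psi = rep(tau0, 4), b = rep(0, 6)))
    if (lambda_est) {
      mid <- mean(transform$prior)
      ini$lambda <- if (abs(mid) < 1e-6) 0.1 else mid
    }
    ini
  })

  jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                          n.chains = chains, n.adapt = max(100, warmup %/% 2),
                          quiet = quiet)
  burn <- max(0, warmup - max(100, warmup %/% 2))
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  mc <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                            progress.bar = "none")
  draws <- as.matrix(mc)
  draws <- rename_draws(draws, structure, cov_info)

  fit <- structure(list(
    draws = draws, mcmc = mc, data = data, structure = structure,
    transform = transform, covariates = covariates,
    covariate_centers = cov_info$centers, priors = priors,
    chains = chains, warmup = warmup, iter = iter, thin = thin, seed = seed,
    model_code = code), class = "dta_fit")
  fit$diagnostics <- convergence_report(fit)
  fit$dic <- compute_dic(fit)
  fit
}

# Resolve covariate spec into per-target design matrices (study order).
resolve_covariates <- function(data, covariates, center, sids) {
  active_k <- c(0L, 0L, 0L, 0L)
  Z <- vector("list", 4)
  centers <- NULL
  names_k <- vector("list", 4)
  if (!is.null(covariates)) {
    if (is.null(data$covariates))
      stop("model covariates requested but the dataset has no covariate table",
           call. = FALSE)
    bad <- setdiff(names(covariates), c("mu1", "mu2", "sigma1", "sigma2"))
    if (length(bad))
      stop("unknown covariate targets: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cov <- data$covariates
    missing_st <- setdiff(sids, cov$study_id)
    if (length(missing_st))
      stop("covariate values missing for study '", missing_st[1], "'",
           call. = FALSE)
    cov <- cov[match(sids, cov$study_id), , drop = FALSE]
    all_names <- unique(unlist(covariates))
    miss <- setdiff(all_names, names(cov))
    if (length(miss))
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    centers <- vapply(cov[all_names], function(v) if (center) mean(v) else 0,
                      numeric(1))
    tgs <- c("mu1", "mu2", "sigma1", "sigma2")
    for (k in 1:4) {
      nm <- covariates[[tgs[k]]]
      if (!is.null(nm) && length(nm)) {
        active_k[k] <- length(nm)
        Zk <- as.matrix(cov[nm])
        Zk <- sweep(Zk, 2, centers[nm], "-")
        Z[[k]] <- matrix(Zk, ncol = length(nm))
        names_k[[k]] <- nm
      }
    }
  }
  list(active_k = active_k, Z = Z, centers = centers, names = names_k)
}

# Canonicalise draw column names; derive full-structure SDs/correlations
# from the product-normal parameters.
rename_draws <- function(draws, structure, cov_info) {
  cn <- colnames(draws)
  tgs <- c("mu1", "mu2", "sigma1", "sigma2")
  for (k in 1:4) {
    nk <- cov_info$names[[k]]
    if (!is.null(nk))
      for (a in seq_along(nk)) {
        old <- sprintf("alpha_%s[%d]", tgs[k], a)
        cn[cn == old] <- sprintf("alpha_%s[%s]", tgs[k], nk[a])
      }
  }
  # single-covariate targets come back unindexed from coda
  for (k in 1:4) {
    nk <- cov_info$names[[k]]
    if (!is.null(nk) && length(nk) == 1L) {
      old <- sprintf("alpha_%s", tgs[k])
      cn[cn == old] <- sprintf("alpha_%s[%s]", tgs[k], nk[1])
    }
  }
  colnames(draws) <- cn
  if (structure == "full") {
    B <- draws[, paste0("b[", 1:6, "]"), drop = FALSE]
    PS <- draws[, paste0("psi[", 1:4, "]"), drop = FALSE]
    nd <- nrow(draws)
    extra <- matrix(NA_real_, nd, 10)
    colnames(extra) <- c("tau_mu[1]", "tau_mu[2]", "tau_sigma[1]",
                         "tau_sigma[2]", "rho_mu", "rho_mu1s1", "rho_mu1s2",
                         "rho_mu2s1", "rho_mu2s2", "rho_s")
    for (r in seq_len(nd)) {
      S <- pn_sigma(B[r, ], PS[r, ])
      sd4 <- sqrt(diag(S))
      R <- S / tcrossprod(sd4)
      extra[r, ] <- c(sd4, R[1, 2], R[1, 3], R[1, 4], R[2, 3], R[2, 4],
                      R[3, 4])
    }
    draws <- cbind(draws, extra)
  }
  draws
}

# Covariance implied by the product-normal (sequential regression)
# parameterisation: d = Bd + diag(psi) eps with B strictly lower
# triangular holding (b21; b31 b32; b41 b42 b43).
pn_sigma <- function(b, psi) {
  B <- matrix(0, 4, 4)
  B[2, 1] <- b[1]
  B[3, 1:2] <- b[2:3]
  B[4, 1:3] <- b[4:6]
  A <- solve(diag(4) - B)
  A %*% diag(psi^2) %*% t(A)
}

#' Posterior draws of fitted positive-test rates
#'
#' For every retained draw and every observation row (study x group x
#' threshold) computes the model's unconditional positive-test probability
#' and the conditional binomial probability used by the factorised
#' likelihood.
#'
#' @param fit a [fit_dta()] result.
#' @param data dataset (defaults to the one stored in the fit).
#' @return list with `pr` and `p_cond` (draws x observations matrices) and
#'   the observation table `obs`.
#' @keywords internal
fitted_rate_draws <- function(fit, data = fit$data) {
  ot <- obs_table(data)
  dr <- fit$draws
  nd <- nrow(dr)
  mu_cols <- sprintf("mu[%d,%d]", ot$study, ot$group)
  ls_cols <- sprintf("logsigma[%d,%d]", ot$study, ot$group)
  MU <- dr[, mu_cols, drop = FALSE]
  SG <- exp(dr[, ls_cols, drop = FALSE])
  if (fit$transform$mode == "estimated") {
    lam <- dr[, "lambda"]
    lc <- log(ot$threshold)
    GC <- (exp(outer(lam, lc)) - 1) / lam  # (C^lam - 1)/lam, draws x obs
  } else {
    GC <- matrix(boxcox(ot$threshold, fit$transform$lambda),
                 nd, nrow(ot), byrow = TRUE)
  }
  PR <- clip_p(stats::plogis((MU - GC) / SG))
  PC <- PR
  idx <- which(ot$first == 0)
  PC[, idx] <- clip_p(PR[, idx, drop = FALSE] /
                        PR[, ot$prev[idx], drop = FALSE])
  list(pr = PR, p_cond = PC, obs = ot)
}

#' Deviance Information Criterion from the factorised likelihood
#'
#' Computes `Dbar` (posterior mean of the residual deviance over the
#' conditional binomial terms), the effective number of parameters
#' `pD = Dbar - D(plug-in)` with the plug-in deviance evaluated at the
#' posterior means of the conditional binomial probabilities (the direct
#' parents of the likelihood), and `DIC = Dbar + pD`. Lower DIC indicates
#' better fit after penalising complexity. A negative `pD` (a known DIC
#' pathology) triggers a warning recorded on the result.
#'
#' @param fit a [fit_dta()] result.
#' @param data dataset (defaults to the one stored in the fit).
#' @return list with `Dbar`, `pD`, `dic` and possibly `warning`.
#' @export
compute_dic <- function(fit, data = fit$data) {
  fr <- fitted_rate_draws(fit, data)
  ot <- fr$obs
  x <- ot$count_above; n <- ot$trials
  dev_draw <- apply(fr$p_cond, 1, function(p) deviance_cells(x, n, p))
  Dbar <- mean(dev_draw)
  Dhat <- deviance_cells(x, n, colMeans(fr$p_cond))
  pD <- Dbar - Dhat
  out <- list(Dbar = Dbar, pD = pD, dic = Dbar + pD)
  if (pD < 0) {
    out$warning <- "pD < 0: plug-in deviance exceeds the posterior mean"
    warning(out$warning, call. = FALSE)
  }
  out
}

#' Convergence diagnostics table
#'
#' Per-parameter potential scale reduction factor (R-hat, requires at
#' least two chains) and effective sample size. Because the Box-Cox
#' parameter mixes slowly (high autocorrelation is expected for it), the
#' `lambda` row is placed first whenever it is present so its effective
#' sample size is seen before anything else.
#'
#' @param fit a [fit_dta()] result.
#' @param rhat_limit threshold above which a parameter is flagged.
#' @return data frame with columns `param`, `rhat`, `ess`, `pass`.
#' @export
convergence_report <- function(fit, rhat_limit = 1.05) {
  mc <- fit$mcmc
  ess <- coda::effectiveSize(mc)
  rhat <- rep(NA_real_, length(ess))
  names(rhat) <- names(ess)
  if (coda::nchain(mc) >= 2) {
    gd <- try(coda::gelman.diag(mc, autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1], silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[names(gd)] <- gd
  }
  out <- data.frame(param = names(ess), rhat = unname(rhat),
                    ess = unname(ess),
                    pass = is.na(rhat) | unname(rhat) < rhat_limit,
                    stringsAsFactors = FALSE)
  if ("lambda" %in% out$param)
    out <- rbind(out[out$param == "lambda", ], out[out$param != "lambda", ])
  rownames(out) <- NULL
  out
}

#' @export
print.dta_fit <- function(x, ...) {
  cat("Multi-threshold test accuracy meta-analysis fit\n")
  cat(sprintf("  structure: %s; transform: %s%s\n", x$structure,
              x$transform$mode,
              if (x$transform$mode == "fixed")
                sprintf(" (lambda = %g)", x$transform$lambda) else ""))
  cat(sprintf("  %d chains x %d iterations (thin %d), seed %s\n",
              x$chains, x$iter, x$thin, format(x$seed)))
  hp <- c("m_mu[1]", "m_mu[2]", "m_sigma[1]", "m_sigma[2]",
          "tau_mu[1]", "tau_mu[2]", "tau_sigma[1]", "tau_sigma[2]")
  hp <- hp[hp %in% colnames(x$draws)]
  if ("lambda" %in% colnames(x$draws)) hp <- c(hp, "lambda")
  qs <- t(apply(x$draws[, hp, drop = FALSE], 2, stats::quantile,
                c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  print(round(qs, 3))
  cat(sprintf("  DIC: Dbar = %.1f, pD = %.1f, DIC = %.1f\n",
              x$dic$Dbar, x$dic$pD, x$dic$dic))
  bad <- x$diagnostics[!x$diagnostics$pass, , drop = FALSE]
  if (nrow(bad))
    cat(sprintf("  convergence: %d parameter(s) with R-hat above limit\n",
                nrow(bad)))
  invisible(x)
}

#' Build a fit object from a draws matrix
#'
#' Constructs a minimal `"dta_fit"` from an explicit matrix of posterior
#' draws with canonical column names (`m_mu[1]`, `m_sigma[2]`,
#' `tau_mu[1]`, `rho_mu`, `lambda`, `mu[i,j]`, `logsigma[i,j]`, ...).
#' Useful for evaluating summary curves at known parameter values (e.g. a
#' point-mass posterior) without running MCMC.
#'
#' @param draws numeric matrix of draws.
#' @param structure between-study structure the draws correspond to.
#' @param transform a [transform_spec]; if the transform is `"estimated"`
#'   the draws must contain a `lambda` column.
#' @param data optional [dta_data] the draws refer to.
#' @return a `"dta_fit"` object (without `mcmc`, diagnostics or DIC).
#' @export
as_dta_fit <- function(draws, structure = "independence",
                       transform = transform_spec(), data = NULL) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  if (transform$mode == "estimated" && !"lambda" %in% colnames(draws))
    stop("estimated transform requires a `lambda` column in draws",
         call. = FALSE)
  structure(list(draws = draws, mcmc = NULL, data = data,
                 structure = structure, transform = transform,
                 covariates = NULL, covariate_centers = NULL,
                 priors = prior_config(), chains = 1L,
                 iter = nrow(draws), thin = 1L, seed = NA_integer_),
            class = "dta_fit")
}
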