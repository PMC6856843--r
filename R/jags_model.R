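# Internal: assemble the JAGS model code for a given configuration.
#
# The likelihood is the binomial factorisation of the per-study-group
# multinomials: the count above the first threshold is binomial out of N,
# each later count binomial out of the previous count with probability
# pr_t / pr_{t-1}. pr is the logistic exceedance probability at the
# Box-Cox-transformed threshold. Between-study structures:
#   independence - four independent normal random-effect sets;
#   structured   - conditional decomposition with two free correlations
#                  (locations; each location with its own log-scale);
#   full         - product-normal (sequential conditional regression)
#                  parameterisation of the dense quadrivariate normal,
#                  guaranteeing positive definiteness by construction; the
#                  implied SDs/correlations are derived after sampling.
jags_model_code <- function(structure, lambda_estimated, active_k, priors,
                            lambda_prior = c(-3, 3)) {
  prec0 <- sprintf("%.10g", priors$mean_sd^-2)
  tau_up <- sprintf("%.10g", priors$tau_upper)
  gC_line <- if (lambda_estimated)
    "    gC[n] <- (pow(Cth[n], lambda) - 1) / lambda" else
    "    # gC supplied as data"
  lik <- c(
    "  for (n in 1:Nobs) {",
    gC_line,
    "    logit(pr[n]) <- (mu[s[n], jg[n]] - gC[n]) / sigma[s[n], jg[n]]",
    "    p[n] <- ifelse(first[n] == 1, pr[n], pr[n] / pr[prev[n]])",
    "    x[n] ~ dbin(p[n], trials[n])",
    "  }")
  off <- character(0)
  tg <- c("mu1", "mu2", "sigma1", "sigma2")
  for (k in 1:4) {
    nm <- paste0("off", tg[k])
    if (active_k[k] > 0) {
      off <- c(off, sprintf(
        "    %s[i] <- inprod(alpha_%s[1:%d], Z%d[i, 1:%d])",
        nm, tg[k], active_k[k], k, active_k[k]))
    } else {
      off <- c(off, sprintf("    %s[i] <- 0", nm))
    }
  }
  means <- c(
    "    mmu1[i] <- m_mu[1] + offmu1[i]",
    "    mmu2[i] <- m_mu[2] + offmu2[i]",
    "    msg1[i] <- m_sigma[1] + offsigma1[i]",
    "    msg2[i] <- m_sigma[2] + offsigma2[i]")
  ranef <- switch(structure,
    independence = c(
      "    mu[i,1] ~ dnorm(mmu1[i], prec_mu1)",
      "    mu[i,2] ~ dnorm(mmu2[i], prec_mu2)",
      "    logsigma[i,1] ~ dnorm(msg1[i], prec_sg1)",
      "    logsigma[i,2] ~ dnorm(msg2[i], prec_sg2)"),
    structured = c(
      "    mu[i,1] ~ dnorm(mmu1[i], prec_mu1)",
      "    cm2[i] <- mmu2[i] + rho_mu * (tau_mu[2] / tau_mu[1]) * (mu[i,1] - mmu1[i])",
      "    mu[i,2] ~ dnorm(cm2[i], prec_c2)",
      "    cs1[i] <- msg1[i] + rho_musig * (tau_sigma[1] / tau_mu[1]) * (mu[i,1] - mmu1[i])",
      "    logsigma[i,1] ~ dnorm(cs1[i], prec_cs1)",
      "    cs2[i] <- msg2[i] + rho_musig * (tau_sigma[2] / tau_mu[2]) * (mu[i,2] - mmu2[i])",
      "    logsigma[i,2] ~ dnorm(cs2[i], prec_cs2)"),
    full = c(
      "    mu[i,1] ~ dnorm(mmu1[i], prec_pn1)",
      "    d1[i] <- mu[i,1] - mmu1[i]",
      "    mu[i,2] ~ dnorm(mmu2[i] + b[1] * d1[i], prec_pn2)",
      "    d2[i] <- mu[i,2] - mmu2[i]",
      "    logsigma[i,1] ~ dnorm(msg1[i] + b[2] * d1[i] + b[3] * d2[i], prec_pn3)",
      "    d3[i] <- logsigma[i,1] - msg1[i]",
      "    logsigma[i,2] ~ dnorm(msg2[i] + b[4] * d1[i] + b[5] * d2[i] + b[6] * d3[i], prec_pn4)"))
  scale_lines <- c(
    "    sigma[i,1] <- exp(logsigma[i,1])",
    "    sigma[i,2] <- exp(logsigma[i,2])")
  hyper <- c(
    sprintf("  m_mu[1] ~ dnorm(0, %s)", prec0),
    sprintf("  m_mu[2] ~ dnorm(0, %s)", prec0),
    sprintf("  m_sigma[1] ~ dnorm(0, %s)", prec0),
    sprintf("  m_sigma[2] ~ dnorm(0, %s)", prec0))
  hyper <- c(hyper, switch(structure,
    independence = c(
      sprintf("  tau_mu[1] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_mu[2] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_sigma[1] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_sigma[2] ~ dunif(0, %s)", tau_up),
      "  prec_mu1 <- pow(tau_mu[1], -2)",
      "  prec_mu2 <- pow(tau_mu[2], -2)",
      "  prec_sg1 <- pow(tau_sigma[1], -2)",
      "  prec_sg2 <- pow(tau_sigma[2], -2)"),
    structured = c(
      sprintf("  tau_mu[1] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_mu[2] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_sigma[1] ~ dunif(0, %s)", tau_up),
      sprintf("  tau_sigma[2] ~ dunif(0, %s)", tau_up),
      "  rho_mu ~ dunif(-1, 1)",
      "  rho_musig ~ dunif(-1, 1)",
      "  prec_mu1 <- pow(tau_mu[1], -2)",
      "  prec_c2 <- 1 / ((1 - pow(rho_mu, 2)) * pow(tau_mu[2], 2))",
      "  prec_cs1 <- 1 / ((1 - pow(rho_musig, 2)) * pow(tau_sigma[1], 2))",
      "  prec_cs2 <- 1 / ((1 - pow(rho_musig, 2)) * pow(tau_sigma[2], 2))"),
    full = c(
      sprintf("  for (k in 1:4) { psi[k] ~ dunif(0, %s) }", tau_up),
      sprintf("  for (k in 1:6) { b[k] ~ dnorm(0, %s) }", prec0),
      "  prec_pn1 <- pow(psi[1], -2)",
      "  prec_pn2 <- pow(psi[2], -2)",
      "  prec_pn3 <- pow(psi[3], -2)",
      "  prec_pn4 <- pow(psi[4], -2)")))
  for (k in 1:4) {
    if (active_k[k] > 0)
      hyper <- c(hyper, sprintf(
        "  for (a in 1:%d) { alpha_%s[a] ~ dnorm(0, %s) }",
        active_k[k], tg[k], prec0))
  }
  if (lambda_estimated)
    hyper <- c(hyper, sprintf("  lambda ~ dunif(%.10g, %.10g)",
                              lambda_prior[1], lambda_prior[2]))
  paste(c("model {",
          lik,
          "  for (i in 1:Nstud) {",
          off, means, ranef, scale_lines,
          "  }",
          hyper,
          "}"), collapse = "\n")
}
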