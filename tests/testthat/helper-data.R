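# Shared fixtures, built in code.

# a small two-study dataset with both groups and two thresholds each
tiny_counts <- function() {
  data.frame(
    study_id = rep(c("s1", "s2"), each = 4),
    group = rep(c(1, 1, 2, 2), 2),
    N = rep(c(100, 100, 80, 80), 2),
    threshold = rep(c(50, 200), 4),
    count_above = c(40, 10, 70, 50, 35, 12, 60, 45))
}

tiny_data <- function() dta_data(tiny_counts())

# random valid study-group count series under the model, for oracle tests
random_instance <- function() {
  Tn <- sample(1:9, 1)
  N <- sample(5:10000, 1)
  thr <- sort(exp(runif(Tn, log(10), log(1000))))
  mu <- runif(1, 2, 7)
  sigma <- exp(runif(1, -1, 1))
  lam <- runif(1, -1, 1)
  pr <- positive_rate(mu, sigma, boxcox(thr, lam))
  x <- integer(Tn)
  x[1] <- rbinom(1, N, pr[1])
  if (Tn > 1) for (t in 2:Tn)
    x[t] <- if (x[t - 1] > 0) rbinom(1, x[t - 1], pr[t] / pr[t - 1]) else 0L
  list(N = N, counts = x, thresholds = thr, mu = mu, sigma = sigma,
       lam = lam)
}

# a fit whose posterior is a point mass at known hyperparameters
point_fit <- function(hp, structure = "independence", n_draws = 3,
                      data = NULL) {
  cols <- c("m_mu[1]" = hp$m_mu[1], "m_mu[2]" = hp$m_mu[2],
            "m_sigma[1]" = hp$m_sigma[1], "m_sigma[2]" = hp$m_sigma[2],
            "tau_mu[1]" = hp$tau_mu[1], "tau_mu[2]" = hp$tau_mu[2],
            "tau_sigma[1]" = hp$tau_sigma[1], "tau_sigma[2]" = hp$tau_sigma[2])
  if (structure == "structured")
    cols <- c(cols, "rho_mu" = rho0(hp, "rho_mu"),
              "rho_musig" = rho0(hp, "rho_musig"))
  draws <- matrix(rep(cols, each = n_draws), nrow = n_draws,
                  dimnames = list(NULL, names(cols)))
  tr <- transform_spec("fixed", lambda = hp$lambda)
  as_dta_fit(draws, structure = structure, transform = tr, data = data)
}

rho0 <- function(hp, nm) if (is.null(hp$rho[[nm]])) 0 else hp$rho[[nm]]

# closed-form summary rates at given hyperparameters
truth_rates <- function(hp, grid) {
  g <- boxcox(grid, hp$lambda)
  list(fpr = plogis((hp$m_mu[1] - g) / exp(hp$m_sigma[1])),
       tpr = plogis((hp$m_mu[2] - g) / exp(hp$m_sigma[2])))
}
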