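hp_base <- function(rho = list(), lambda = 0)
  hyperparams(m_mu = c(4.5, 6.5), m_sigma = c(-0.2, 0.1),
              tau_mu = c(0.6, 0.5), tau_sigma = c(0.3, 0.25),
              rho = rho, lambda = lambda)

test_that("structured and full densities nest to independence at rho = 0", {
  e <- c(4.1, 6.9, -0.5, 0.3)
  hp0 <- hp_base()
  l_ind <- ranef_logpdf(e, hp0, "independence")
  l_str <- ranef_logpdf(e, hp_base(list(rho_mu = 0, rho_musig = 0)),
                        "structured")
  l_ful <- ranef_logpdf(e, hp0, "full")
  expect_equal(l_str, l_ind, tolerance = 1e-12)
  expect_equal(l_ful, l_ind, tolerance = 1e-12)
})

test_that("full-structure density matches a dense multivariate normal oracle", {
  hp <- hp_base(list(rho_mu = 0.5, rho_mu1s1 = 0.3, rho_mu2s2 = -0.2,
                     rho_s = 0.4))
  e <- c(5.0, 6.0, -0.4, 0.5)
  S <- between_study_sigma(hp, "full")
  m <- c(hp$m_mu, hp$m_sigma)
  oracle <- -0.5 * t(e - m) %*% solve(S) %*% (e - m) -
    0.5 * log(det(S)) - 2 * log(2 * pi)
  expect_equal(ranef_logpdf(e, hp, "full"), drop(oracle), tolerance = 1e-12)
})

test_that("structured density equals its implied dense normal", {
  hp <- hp_base(list(rho_mu = 0.7, rho_musig = 0.4))
  e <- c(4.0, 6.8, 0.1, -0.3)
  S <- between_study_sigma(hp, "structured")
  m <- c(hp$m_mu, hp$m_sigma)
  oracle <- -0.5 * t(e - m) %*% solve(S) %*% (e - m) -
    0.5 * log(det(S)) - 2 * log(2 * pi)
  expect_equal(ranef_logpdf(e, hp, "structured"), drop(oracle),
               tolerance = 1e-10)
})

test_that("non-positive-definite full correlation matrices are rejected", {
  hp <- hp_base(list(rho_mu = 0.95, rho_mu1s1 = 0.95, rho_mu2s1 = -0.95))
  expect_error(between_study_sigma(hp, "full"), "positive definite")
  expect_error(ranef_logpdf(c(4, 6, 0, 0), hp, "full"), "positive definite")
})

test_that("covariates shift the random-effect means linearly", {
  hp <- hp_base()
  hp$alpha <- list(mu1 = c(age = 0.05), mu2 = c(age = 0.02))
  z <- c(age = 10)
  e <- c(4.5 + 0.5, 6.5 + 0.2, -0.2, 0.1)
  hp_shifted <- hp_base()
  hp_shifted$m_mu <- hp$m_mu + c(0.5, 0.2)
  expect_equal(ranef_logpdf(e, hp, "independence", z = z),
               ranef_logpdf(e, hp_shifted, "independence"),
               tolerance = 1e-12)
})

test_that("sampled effects degenerate to the means when tau = 0", {
  hp <- hyperparams(c(4, 6), c(0, 0), c(0, 0), c(0, 0))
  eff <- sample_study_effects(hp, "independence", n = 5, seed = 1)
  expect_equal(unname(eff),
               matrix(rep(c(4, 6, 0, 0), each = 5), 5), tolerance = 1e-12)
})

test_that("structured sampling reproduces the requested correlation", {
  hp <- hp_base(list(rho_mu = 0.99, rho_musig = 0))
  eff <- sample_study_effects(hp, "structured", n = 1e4, seed = 42)
  expect_equal(cor(eff[, "mu1"], eff[, "mu2"]), 0.99, tolerance = 0.02)
})

test_that("sample moments match hyperparameters within Monte Carlo error", {
  hp <- hp_base(list(rho_mu = 0.6, rho_musig = 0.3))
  n <- 1e4
  for (st in c("independence", "structured", "full")) {
    hh <- if (st == "full")
      hp_base(list(rho_mu = 0.6, rho_mu1s1 = 0.3, rho_mu2s2 = 0.3)) else hp
    eff <- sample_study_effects(hh, st, n = n, seed = 9)
    m_true <- c(hh$m_mu, hh$m_sigma)
    sd_true <- c(hh$tau_mu, hh$tau_sigma)
    for (k in 1:4) {
      se <- sd_true[k] / sqrt(n)
      expect_lt(abs(mean(eff[, k]) - m_true[k]), 3.5 * se)
      expect_lt(abs(sd(eff[, k]) - sd_true[k]), 3.5 * sd_true[k] / sqrt(2 * n))
    }
  }
})

test_that("structured implied covariance equals the sample covariance", {
  hp <- hp_base(list(rho_mu = 0.7, rho_musig = 0.45))
  S <- between_study_sigma(hp, "structured")
  eff <- sample_study_effects(hp, "structured", n = 4e4, seed = 3)
  Shat <- cov(eff)
  expect_true(max(abs(Shat - S)) < 0.02)
})

test_that("prior enumeration counts the free parameters of each model", {
  expect_length(build_prior(prior_config(), "independence"), 8)
  expect_length(build_prior(prior_config(), "independence",
                            transform = transform_spec("estimated")), 9)
  expect_length(build_prior(prior_config(), "full"), 14)
  expect_length(build_prior(prior_config(), "structured"), 10)
  pr <- build_prior(prior_config(), "structured",
                    covariate_targets = list(mu1 = "age", mu2 = "age"))
  expect_length(pr, 12)
  expect_equal(pr[["alpha_mu1[age]"]]$dist, "normal")
  expect_equal(pr[["tau_mu[1]"]]$pars[["high"]], 5)
  expect_equal(pr[["rho_mu"]]$pars[["low"]], -1)
})
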