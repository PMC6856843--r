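test_that("a point-mass posterior reproduces the closed-form summary curve", {
  hp <- hyperparams(c(4.5, 6.5), c(-0.2, 0.1), c(0, 0), c(0, 0))
  fit <- point_fit(hp)
  grid <- exp(seq(log(20), log(2000), length.out = 120))
  sc <- summary_curve(fit, grid)
  tr <- truth_rates(hp, grid)
  expect_equal(sc$fpr, tr$fpr, tolerance = 1e-12)
  expect_equal(sc$tpr, tr$tpr, tolerance = 1e-12)
  expect_equal(sc$fpr_lo, sc$fpr_hi, tolerance = 1e-12)
  # a draw with m_mu1 = g(C*) puts the summary fpr at exactly 1/2
  cstar <- exp(hp$m_mu[1])
  sc2 <- summary_curve(fit, grid = c(cstar * 0.99, cstar, cstar * 1.01))
  expect_equal(sc2$fpr[2], 0.5, tolerance = 1e-12)
})

test_that("summary rates decrease strictly in threshold at all quantiles", {
  hp <- hyperparams(c(4.5, 6.5), c(-0.2, 0.1), c(0.4, 0.4), c(0.2, 0.2))
  set.seed(31)
  draws <- cbind(
    "m_mu[1]" = rnorm(500, 4.5, 0.2), "m_mu[2]" = rnorm(500, 6.5, 0.2),
    "m_sigma[1]" = rnorm(500, -0.2, 0.1), "m_sigma[2]" = rnorm(500, 0.1, 0.1),
    "tau_mu[1]" = runif(500, 0.2, 0.6), "tau_mu[2]" = runif(500, 0.2, 0.6),
    "tau_sigma[1]" = runif(500, 0.1, 0.3), "tau_sigma[2]" = runif(500, 0.1, 0.3))
  fit <- as_dta_fit(draws, "independence", transform_spec("fixed", 0))
  sc <- summary_curve(fit, exp(seq(log(20), log(2000), length.out = 80)))
  for (cl in c("fpr", "fpr_lo", "fpr_hi", "tpr", "tpr_lo", "tpr_hi"))
    expect_true(all(diff(sc[[cl]]) < 0), info = cl)
})

test_that("prediction intervals equal credible intervals when tau = 0", {
  hp <- hyperparams(c(4.5, 6.5), c(-0.2, 0.1), c(0, 0), c(0, 0))
  fit <- point_fit(hp, n_draws = 50)
  pc <- prediction_curve(fit, exp(seq(log(30), log(1500), length.out = 60)),
                         seed = 4)
  expect_equal(pc$fpr_pi_lo, pc$fpr_lo, tolerance = 1e-10)
  expect_equal(pc$tpr_pi_hi, pc$tpr_hi, tolerance = 1e-10)
})

test_that("heterogeneity widens prediction intervals beyond credible ones", {
  # point-mass hyperparameters but a large between-study SD on the
  # disease-free location: CrI width is ~0, PI width is substantial
  hp <- hyperparams(c(4.5, 6.5), c(-0.2, 0.1), c(1.2, 0.3), c(0.2, 0.2))
  fit <- point_fit(hp, n_draws = 2000)
  grid <- exp(seq(log(30), log(300), length.out = 40))
  pc <- prediction_curve(fit, grid, seed = 8)
  expect_true(all(pc$fpr_pi_hi - pc$fpr_pi_lo + 1e-9 >=
                    pc$fpr_hi - pc$fpr_lo))
  w_pi <- pc$fpr_pi_hi - pc$fpr_pi_lo
  w_cri <- pc$fpr_hi - pc$fpr_lo
  expect_gt(min(w_pi / pmax(w_cri, 1e-6)), 1.5)
  expect_true(all(pc$fpr_pi_lo >= 0 & pc$fpr_pi_hi <= 1))
  expect_true(all(pc$tpr_pi_lo >= 0 & pc$tpr_pi_hi <= 1))
})

test_that("SROC geometry follows the two-distribution algebra", {
  grid <- exp(seq(log(0.01), log(1e7), length.out = 300))
  # identical populations: the curve lies on the diagonal
  hp_eq <- hyperparams(c(5, 5), c(0.2, 0.2), c(0, 0), c(0, 0))
  sr <- sroc_curve(point_fit(hp_eq), grid)
  expect_equal(sr$tpr, sr$fpr, tolerance = 1e-12)
  # equal scales: constant logit difference along the curve
  hp_sh <- hyperparams(c(4, 6), c(0.3, 0.3), c(0, 0), c(0, 0))
  sr2 <- sroc_curve(point_fit(hp_sh), grid)
  d <- qlogis(sr2$tpr) - qlogis(sr2$fpr)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-8)
  expect_true(all(diff(sr2$fpr) < 0) && all(diff(sr2$tpr) < 0))
  # endpoints approach (0,0) and (1,1) as the grid extends
  expect_lt(sr2$fpr[300], 0.01)
  expect_gt(sr2$tpr[1], 0.99)
})

test_that("Youden optimum sits midway between symmetric populations", {
  # logistic populations at 0 and 2 with unit scale, identity transform:
  # the maximal tpr - fpr occurs where g(C) = 1, i.e. C = 2
  hp <- hyperparams(c(0, 2), c(0, 0), c(0, 0), c(0, 0), lambda = 1)
  fit <- point_fit(hp)
  grid <- seq(0.05, 5, length.out = 1000)
  sc <- summary_curve(fit, grid)
  opt <- youden_optimal(sc)
  expect_equal(opt$threshold - 1, 1.0, tolerance = 0.01)
  # a useless test (identical populations) has maximal index ~ 0
  hp0 <- hyperparams(c(1, 1), c(0, 0), c(0, 0), c(0, 0), lambda = 1)
  opt0 <- youden_optimal(summary_curve(point_fit(hp0), grid))
  expect_equal(opt0$youden, 0, tolerance = 1e-10)
})

test_that("raising the sensitivity weight never raises the optimum", {
  hp <- hyperparams(c(4, 6), c(0.2, 0.4), c(0, 0), c(0, 0))
  sc <- summary_curve(point_fit(hp), exp(seq(log(5), log(3000),
                                             length.out = 500)))
  opts <- vapply(seq(0.2, 0.8, by = 0.1),
                 function(w) youden_optimal(sc, w)$threshold, numeric(1))
  expect_true(all(diff(opts) <= 1e-9))
})

test_that("covariate ratios exponentiate the regression coefficient", {
  draws <- cbind("m_mu[1]" = rep(4, 100), "m_mu[2]" = rep(6, 100),
                 "m_sigma[1]" = 0, "m_sigma[2]" = 0,
                 "tau_mu[1]" = 0.1, "tau_mu[2]" = 0.1,
                 "tau_sigma[1]" = 0.1, "tau_sigma[2]" = 0.1,
                 "alpha_mu1[age]" = rep(0.0279, 100))
  fit <- as_dta_fit(draws, "independence", transform_spec("fixed", 0))
  r <- covariate_ratio(fit, "age", 5, "disease_free")
  expect_equal(r$ratio, exp(0.0279 * 5), tolerance = 1e-12)
  expect_equal(r$ratio, 1.15, tolerance = 1e-3)
  r0 <- covariate_ratio(fit, "age", 0, "disease_free")
  expect_identical(r0$ratio, 1)
  # ratio interpretation is log-scale only
  fit1 <- as_dta_fit(draws, "independence", transform_spec("fixed", 1))
  expect_error(covariate_ratio(fit1, "age", 5, "disease_free"), "log")
})

test_that("grids beyond the observed range are flagged", {
  sim <- simulate_dta(scenario_spec(n_studies = 4), seed = 12)
  hp <- default_truth()
  fit <- point_fit(hp, data = sim$data)
  rng <- range(sim$data$counts$threshold)
  expect_warning(summary_curve(fit, c(rng[1] / 2, rng[1], rng[2])),
                 "extrapolat")
  sc <- suppressWarnings(summary_curve(fit, c(rng[1] / 2, rng[1], rng[2])))
  expect_true(attr(sc, "extrapolated"))
})
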