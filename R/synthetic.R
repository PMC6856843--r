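#' Scenario specification for the synthetic-data generator
#'
#' Describes a simulated multi-threshold meta-analysis. The defaults
#' emulate a natriuretic-peptide-style biomarker meta-analysis: around
#' 18 studies of 50-500 patients per disease group, each reporting between
#' one and seven thresholds drawn from a common log-spaced ladder, with
#' log-logistic (Box-Cox parameter 0) underlying test results, the
#' diseased population shifted upwards by roughly 1.8 natural-log units,
#' and moderate between-study heterogeneity in all four location/scale
#' parameters.
#'
#' @param n_studies number of studies.
#' @param N_range length-2 integer range of group sizes (drawn uniformly,
#'   independently per group); a single value fixes all group sizes.
#' @param thresholds_per_study length-2 integer range of the number of
#'   thresholds a study reports (1-9 is typical of real reviews).
#' @param threshold_range positive length-2 range spanned by the common
#'   threshold ladder.
#' @param ladder_size number of rungs on the common log-spaced threshold
#'   ladder from which studies sample their cutoffs.
#' @param hyperparams a [hyperparams] object: the generative truth.
#' @param structure between-study structure used to draw study effects.
#' @param missingness probability in `[0, 1)` that a study-group omits any
#'   given interior threshold (the first and last reported threshold are
#'   always kept, so every study-group retains at least one).
#' @return list of class `"dta_scenario"`.
#' @export
scenario_spec <- function(n_studies = 18, N_range = c(50, 500),
                          thresholds_per_study = c(1, 7),
                          threshold_range = c(25, 2000), ladder_size = 12,
                          hyperparams = default_truth(),
                          structure = "independence", missingness = 0) {
  stopifnot(n_studies >= 1, all(N_range >= 1),
            thresholds_per_study[1] >= 1,
            all(threshold_range > 0), ladder_size >= max(thresholds_per_study),
            missingness >= 0, missingness < 1)
  if (length(N_range) == 1) N_range <- c(N_range, N_range)
  if (length(thresholds_per_study) == 1)
    thresholds_per_study <- rep(thresholds_per_study, 2)
  structure(list(n_studies = n_studies, N_range = N_range,
                 thresholds_per_study = thresholds_per_study,
                 threshold_range = threshold_range, ladder_size = ladder_size,
                 hyperparams = hyperparams, structure = structure,
                 missingness = missingness),
            class = "dta_scenario")
}

#' Default generative truth
#'
#' Hyperparameters used by the default [scenario_spec()]: on the natural-
#' log scale the disease-free population is centred at `m_mu = 4.4`
#' (biomarker values around 80) and the diseased population at 6.2
#' (around 500), both with logistic scale around `exp(-0.1)`; between-study
#' SDs of 0.6/0.5 on the locations and 0.25 on the log-scales; Box-Cox
#' parameter 0 (log-logistic results).
#'
#' @return a [hyperparams] object.
#' @export
default_truth <- function() {
  hyperparams(m_mu = c(4.4, 6.2), m_sigma = c(-0.1, -0.1),
              tau_mu = c(0.6, 0.5), tau_sigma = c(0.25, 0.25), lambda = 0)
}

#' Generate a synthetic multi-threshold dataset
#'
#' Draws a dataset from the model's own generative process: study-level
#' random effects from the between-study distribution
#' ([sample_study_effects()]), study-specific threshold sets as random
#' subsets of a common log-spaced ladder, positive-test probabilities from
#' the logistic exceedance link at the Box-Cox-transformed thresholds, and
#' counts sampled sequentially through the conditional binomial chain (so
#' generated counts are monotone by construction). Optional missingness
#' drops interior thresholds per study-group, which also exercises groups
#' reporting different threshold sets.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed (required; the same seed reproduces the
#'   dataset bit-exactly).
#' @return list of class `"dta_sim"` with elements `data` (a [dta_data])
#'   and `truth` (the hyperparameters, per-study effects, and scenario).
#' @export
simulate_dta <- function(spec = scenario_spec(), seed) {
  stopifnot(inherits(spec, "dta_scenario"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  pick <- function(v, n = 1) v[sample.int(length(v), n)]  # no 1:n surprise
  hp <- spec$hyperparams
  eff <- sample_study_effects(hp, spec$structure, n = spec$n_studies)
  ladder <- exp(seq(log(spec$threshold_range[1]), log(spec$threshold_range[2]),
                    length.out = spec$ladder_size))
  rows <- vector("list", 2 * spec$n_studies)
  for (i in seq_len(spec$n_studies)) {
    Ti <- pick(seq(spec$thresholds_per_study[1], spec$thresholds_per_study[2]))
    th <- sort(pick(ladder, Ti))
    for (j in 1:2) {
      keep <- rep(TRUE, Ti)
      if (spec$missingness > 0 && Ti > 1) {
        interior <- setdiff(seq_len(Ti), c(1L, Ti))
        keep[interior] <- stats::runif(length(interior)) >= spec$missingness
      }
      thj <- th[keep]
      N <- pick(seq(spec$N_range[1], spec$N_range[2]))
      mu <- eff[i, j]; sg <- exp(eff[i, j + 2])
      pr <- positive_rate(mu, sg, boxcox(thj, hp$lambda))
      x <- integer(length(thj))
      x[1] <- stats::rbinom(1, N, pr[1])
      for (t in seq_along(thj)[-1])
        x[t] <- if (x[t - 1] > 0)
          stats::rbinom(1, x[t - 1], pr[t] / pr[t - 1]) else 0L
      rows[[(i - 1) * 2 + j]] <- data.frame(
        study_id = sprintf("study%02d", i), group = j, N = N,
        threshold = thj, count_above = x)
    }
  }
  data <- dta_data(do.call(rbind, rows))
  structure(list(data = data,
                 truth = list(hyperparams = hp, effects = eff,
                              scenario = spec, seed = as.integer(seed))),
            class = "dta_sim")
}

#' Generate individual-level test results and the implied count dataset
#'
#' The second, independent generation path: draws raw transformed test
#' results from the logistic distributions, inverts the Box-Cox transform
#' back to the natural scale, and counts results above each threshold.
#' The derived counts follow exactly the same law as the probability-level
#' path in [simulate_dta()], which makes the two paths a cross-check of
#' the exceedance link. Draws whose transformed value falls outside the
#' Box-Cox inversion domain (`lambda * g + 1 <= 0`) are resampled and the
#' number of resamples recorded.
#'
#' @param mu,sigma logistic location and scale of the transformed results
#'   for one population.
#' @param n number of individuals.
#' @param thresholds strictly increasing positive thresholds to count
#'   against.
#' @param lambda Box-Cox parameter.
#' @param seed integer seed.
#' @return list with `results` (natural-scale values), `counts_above`
#'   (integer counts per threshold) and `n_resampled`.
#' @export
simulate_individual <- function(mu, sigma, n, thresholds, lambda = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- stats::rlogis(n, mu, sigma)
  n_res <- 0L
  if (abs(lambda) >= 1e-8) {
    bad <- which(lambda * g + 1 <= 0)
    while (length(bad)) {
      n_res <- n_res + length(bad)
      g[bad] <- stats::rlogis(length(bad), mu, sigma)
      bad <- bad[lambda * g[bad] + 1 <= 0]
      if (n_res > 100 * n)
        stop("Box-Cox inversion domain rejected too many draws; ",
             "check (mu, sigma, lambda)", call. = FALSE)
    }
  }
  y <- boxcox_inv(g, lambda)
  counts <- vapply(thresholds, function(C) sum(y > C), integer(1))
  list(results = y, counts_above = counts, n_resampled = n_res)
}
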