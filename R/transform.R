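#' Box-Cox transformation of a threshold scale
#'
#' Maps a positive test-result threshold `C` to the transformed scale on
#' which the model assumes logistic distributions of test results:
#' \deqn{g(C) = (C^\lambda - 1)/\lambda \quad (\lambda \neq 0), \qquad
#'       g(C) = \log C \quad (\lambda = 0).}
#' `lambda = 1` corresponds to untransformed (shifted) results, i.e. logistic
#' distributions on the natural scale; decreasing `lambda` implies
#' increasingly right-skewed underlying distributions, with `lambda = 0`
#' (natural log) giving log-logistic distributions.
#'
#' The two branches join continuously at `lambda = 0`: for
#' `|lambda| < 1e-8` the log branch is used, and for `|lambda| < 1e-4`
#' a second-order expansion `log C + lambda * log(C)^2 / 2` keeps the
#' evaluation numerically continuous in `lambda`.
#'
#' Thresholds must be strictly positive. A threshold of 0 (or below) is an
#' error, never silently shifted: if a test can yield non-positive values,
#' shifting is the caller's preprocessing decision.
#'
#' @param C numeric vector of strictly positive thresholds.
#' @param lambda single numeric Box-Cox parameter.
#' @return numeric vector `g(C)`, strictly increasing in `C` for every
#'   `lambda`.
#' @examples
#' boxcox(4, 0.5)   # (2 - 1) / 0.5 = 2
#' boxcox(c(1, exp(1)), 0)  # 0, 1
#' @export
boxcox <- function(C, lambda) {
  if (!is.numeric(C) || !is.numeric(lambda) || length(lambda) != 1L)
    stop("`C` must be numeric and `lambda` a single number", call. = FALSE)
  if (length(C) && (any(!is.finite(C)) || any(C <= 0)))
    stop("Box-Cox transform requires strictly positive finite thresholds",
         call. = FALSE)
  lc <- log(C)
  if (abs(lambda) < 1e-8) return(lc)
  if (abs(lambda) < 1e-4) return(lc + lambda * lc^2 / 2)
  (C^lambda - 1) / lambda
}

#' Vectorised Box-Cox transform of a threshold sequence
#'
#' Elementwise [boxcox()]; preserves strict ordering of the input.
#'
#' @param thresholds numeric vector of strictly positive thresholds.
#' @inheritParams boxcox
#' @return numeric vector of transformed thresholds.
#' @export
boxcox_vec <- function(thresholds, lambda) boxcox(thresholds, lambda)

#' Inverse Box-Cox transform
#'
#' Maps a value on the transformed scale back to the natural test-result
#' scale. For `lambda != 0` the inverse `(lambda * g + 1)^(1/lambda)` exists
#' only where `lambda * g + 1 > 0`; values outside that domain return `NA`.
#'
#' @param g numeric vector on the transformed scale.
#' @inheritParams boxcox
#' @return numeric vector on the natural scale (`NA` where undefined).
#' @export
boxcox_inv <- function(g, lambda) {
  if (abs(lambda) < 1e-8) return(exp(g))
  base <- lambda * g + 1
  out <- rep(NA_real_, length(g))
  ok <- base > 0
  out[ok] <- base[ok]^(1 / lambda)
  out
}

#' Transformation specification
#'
#' Describes how the threshold scale is transformed before entering the
#' model: either a fixed Box-Cox parameter (`lambda = 0`, the natural log,
#' is the usual choice for right-skewed biomarkers) or a parameter estimated
#' from the data under a uniform prior (default Uniform(-3, 3); a
#' Uniform(1, 10) sensitivity prior can be requested instead).
#'
#' @param mode `"fixed"` or `"estimated"`.
#' @param lambda fixed value of the Box-Cox parameter (used iff
#'   `mode = "fixed"`).
#' @param prior length-2 numeric, lower/upper bound of the uniform prior on
#'   `lambda` (used iff `mode = "estimated"`).
#' @return a list of class `"dta_transform"`.
#' @export
transform_spec <- function(mode = c("fixed", "estimated"), lambda = 0,
                           prior = c(-3, 3)) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
      stop("fixed `lambda` must be a single finite number", call. = FALSE)
  } else {
    if (length(prior) != 2L || !all(is.finite(prior)) || prior[1] >= prior[2])
      stop("`prior` must be finite bounds with prior[1] < prior[2]",
           call. = FALSE)
  }
  structure(list(mode = mode, lambda = if (mode == "fixed") lambda else NULL,
                 prior = as.numeric(prior)),
            class = "dta_transform")
}
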