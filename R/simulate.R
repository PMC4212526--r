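#' Specify a synthetic screening response
#'
#' Defines the generative truth for simulated screens: a linear
#' main-effects model on coded units, optionally with two-factor
#' interactions, plus homoscedastic Gaussian noise,
#' `y_i = b0 + sum_j beta_j x_ij + sum interactions + N(0, sigma^2)`.
#' Defaults mirror the shipped CHO screen: an intercept near its mean
#' growth rate and noise of the order implied by its residual mean square
#' (sqrt(0.0007) ~ 0.026 d^-1; the default 0.01 d^-1 keeps the probability
#' of clipping at zero negligible).
#'
#' @param intercept baseline response `b0` (d^-1).
#' @param effects named numeric vector of main effects per coded unit
#'   (d^-1); names must be design factor names. A factor at +1 contributes
#'   `+beta_j`, at -1 `-beta_j`, so the high-vs-low mean difference is
#'   `2 beta_j`.
#' @param interactions optional named numeric vector of two-factor
#'   interaction effects, names like `"X1:X4"`.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed RNG seed for [simulate_response()].
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(intercept = 0.24, effects = numeric(0),
                           interactions = NULL, sigma = 0.01, seed = 1L) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            sigma >= 0, is.numeric(effects))
  if (length(effects) && is.null(names(effects))) {
    stop("effects must be named by factor")
  }
  if (!is.null(interactions)) {
    if (is.null(names(interactions)) ||
        !all(grepl("^[^:]+:[^:]+$", names(interactions)))) {
      stop("interactions must be named 'A:B'")
    }
  }
  if (!all(is.finite(c(intercept, effects, interactions %||% 0)))) {
    stop("effects must be finite")
  }
  structure(list(intercept = intercept, effects = effects,
                 interactions = interactions, sigma = sigma, seed = seed),
            class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a screening response with known ground truth
#'
#' Draws one response vector from a [synthetic_spec()] on the given
#' design, reproducibly under the spec's seed. Negative draws are clipped
#' to zero (growth rates are non-negative) with a message reporting the
#' count.
#'
#' @param design a [screen_design()].
#' @param spec a [synthetic_spec()].
#' @return Numeric response vector of length `nrow(design$coded)`.
#' @examples
#' d <- pb_design(12, 7)
#' y <- simulate_response(d, synthetic_spec(effects = c(X4 = 0.04), sigma = 0))
#' range_analysis(d, y)$R[4]   # exactly 2 * 0.04
#' @export
simulate_response <- function(design, spec) {
  stopifnot(inherits(design, "pb_design"), inherits(spec, "synthetic_spec"))
  X <- design$coded
  nms <- colnames(X)
  mu <- rep(spec$intercept, nrow(X))
  if (length(spec$effects)) {
    unknown <- setdiff(names(spec$effects), nms)
    if (length(unknown)) {
      stop("effects reference unknown factor(s): ",
           paste(unknown, collapse = ", "))
    }
    mu <- mu + as.numeric(X[, names(spec$effects), drop = FALSE] %*%
                            spec$effects)
  }
  if (length(spec$interactions)) {
    for (nm in names(spec$interactions)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (!all(pair %in% nms)) {
        stop("interaction '", nm, "' references unknown factor(s)")
      }
      mu <- mu + spec$interactions[[nm]] * X[, pair[1]] * X[, pair[2]]
    }
  }
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(spec$seed)
  }
  y <- mu + stats::rnorm(nrow(X), 0, spec$sigma)
  clipped <- y < 0
  if (any(clipped)) {
    message(sum(clipped), " simulated response(s) clipped at zero")
    y[clipped] <- 0
  }
  y
}

#' Monte-Carlo recovery report for the screening analysis
#'
#' Replicates the screen under a [synthetic_spec()] and summarises, per
#' factor: the fraction of replicates in which the contrast ANOVA declares
#' it significant at `alpha`, and the mean and SD of the estimated effect
#' `(t1 - t2) / 2` against the true coefficient. On orthogonal designs the
#' estimator is exact for `sigma = 0` and unbiased otherwise.
#'
#' @param design a [screen_design()].
#' @param spec a [synthetic_spec()]; its `seed` seeds the replicate
#'   stream.
#' @param n_reps number of replicates, `>= 1`.
#' @param alpha significance level of the per-factor F test.
#' @return A data frame per factor: `factor`, `true_effect`,
#'   `detection_rate`, `mean_estimate`, `sd_estimate`, `bias`; attribute
#'   `n_reps`.
#' @export
recovery_report <- function(design, spec, n_reps = 200, alpha = 0.05) {
  stopifnot(inherits(design, "pb_design"), n_reps >= 1)
  X <- design$coded
  nms <- colnames(X)
  truth <- stats::setNames(rep(0, ncol(X)), nms)
  truth[names(spec$effects)] <- spec$effects
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  hits <- matrix(FALSE, n_reps, ncol(X))
  est <- matrix(NA_real_, n_reps, ncol(X))
  for (r in seq_len(n_reps)) {
    spec_r <- spec; spec_r$seed <- seeds[r]
    y <- suppressMessages(simulate_response(design, spec_r))
    a <- pb_anova(design, y)
    fac <- a[!a$source %in% c("Error", "Total"), ]
    hits[r, ] <- !is.na(fac$p) & fac$p < alpha
    est[r, ] <- as.numeric(crossprod(X, y)) / nrow(X)  # (t1 - t2) / 2
  }
  out <- data.frame(factor = nms, true_effect = as.numeric(truth),
                    detection_rate = colMeans(hits),
                    mean_estimate = colMeans(est),
                    sd_estimate = apply(est, 2, stats::sd),
                    stringsAsFactors = FALSE)
  out$bias <- out$mean_estimate - out$true_effect
  attr(out, "n_reps") <- n_reps
  out
}
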