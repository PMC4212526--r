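#' Mean-impact-value perturbation importance
#'
#' Scores each input variable of a trained predictor by perturbing it
#' +/-`delta` (default 10%) in the training data and averaging the change
#' in model output: column j of the natural-unit matrix is multiplied by
#' `1 + delta` and by `1 - delta`, both perturbed datasets are pushed
#' through the predictor, and
#' `MIV_j = mean(predict(X_plus) - predict(X_minus))`. The sign carries
#' the direction of the effect; ranking uses `|MIV|`.
#'
#' Perturbation is applied in *natural units* (concentrations) and then
#' re-encoded through the model's input scaling. Perturbing coded -1/+1
#' settings directly would be degenerate: multiplying a coded column by
#' `1 +/- delta` shifts the high and low levels in opposite directions, so
#' for any linear effect the two shifts cancel across a balanced design
#' and every MIV is exactly zero. Concentrations are positive, so the
#' natural-unit perturbation does not cancel. See the package vignette for
#' a second, subtler degeneracy affecting near-interpolating RBF models.
#'
#' For a linear predictor `f(u) = sum_j beta_j u_j` in natural units,
#' `MIV_j = 2 * delta * beta_j * mean(u_j)` exactly.
#'
#' @param model either an `"svr_model"` (its factor table provides the
#'   encoding) or a plain function mapping a natural-unit matrix to
#'   predictions.
#' @param X_natural natural-unit training matrix. If `model` is an
#'   `"svr_model"` with a factor table this defaults to the decoded
#'   training inputs.
#' @param delta perturbation fraction in `(0, 1)`; default 0.10.
#' @return A data frame of class `"miv_table"`: `factor`, `MIV`,
#'   `abs_MIV`, `rank` (descending `|MIV|`, ties broken by factor order).
#' @examples
#' scr <- cho_screen()
#' fit <- svr_fit(scr$design$coded, scr$response, C = 2, gamma = 0.05,
#'                factors = scr$design$factors)
#' miv(fit)
#' @export
miv <- function(model, X_natural = NULL, delta = 0.10) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  if (inherits(model, "svr_model")) {
    if (is.null(X_natural)) {
      if (is.null(model$factors)) {
        stop("supply X_natural or fit the model with a factor table")
      }
      X_natural <- decode_levels(model$X, model$factors)
    }
    predictor <- function(U) predict(model, U, units = "natural")
  } else if (is.function(model)) {
    if (is.null(X_natural)) stop("X_natural is required for a function model")
    predictor <- model
  } else {
    stop("model must be an svr_model or a prediction function")
  }
  X_natural <- as.matrix(X_natural)
  nm <- colnames(X_natural)
  if (is.null(nm)) nm <- paste0("X", seq_len(ncol(X_natural)))
  vals <- vapply(seq_len(ncol(X_natural)), function(j) {
    up <- X_natural; up[, j] <- up[, j] * (1 + delta)
    dn <- X_natural; dn[, j] <- dn[, j] * (1 - delta)
    p_up <- tryCatch(predictor(up), error = function(e) {
      stop("prediction failed while perturbing factor '", nm[j], "': ",
           conditionMessage(e))
    })
    p_dn <- predictor(dn)
    mean(p_up - p_dn)
  }, numeric(1))
  out <- data.frame(factor = nm, MIV = vals, abs_MIV = abs(vals),
                    rank = rank(-abs(vals), ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("miv_table", "data.frame")
  out
}

#' Most influential factors by mean impact value
#'
#' @param miv_table a [miv()] table.
#' @param k number of factors, `1 <= k <= nrow(miv_table)`.
#' @return Character vector of the first `k` factor names by descending
#'   `|MIV|` (ties broken by original factor order).
#' @export
miv_top <- function(miv_table, k) {
  stopifnot(inherits(miv_table, "miv_table"))
  if (k < 1 || k > nrow(miv_table)) {
    stop("k must be between 1 and ", nrow(miv_table))
  }
  miv_table$factor[order(miv_table$rank)][seq_len(k)]
}

#' @export
print.miv_table <- function(x, ...) {
  cat("Mean impact values (+/-10%-type perturbation, natural units)\n")
  df <- x
  df$MIV <- signif(df$MIV, 6); df$abs_MIV <- signif(df$abs_MIV, 6)
  print.data.frame(df[order(df$rank), ], row.names = FALSE, ...)
  invisible(x)
}
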