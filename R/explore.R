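# Gray-code corner enumeration: corner i (0-based) has bit pattern
# g = i XOR (i >> 1); bit j-1 set -> factor j at +1, else -1. Successive
# corners differ in exactly one factor.
.gray_corners <- function(k) {
  i <- 0:(2^k - 1)
  g <- bitwXor(i, i %/% 2L)
  out <- matrix(-1, length(g), k)
  for (j in seq_len(k)) out[, j] <- ifelse(bitwAnd(g, 2^(j - 1)) > 0, 1, -1)
  out
}

#' Predictions at the corners of a factor subset
#'
#' Evaluates a fitted surrogate at every high/low combination of a chosen
#' factor subset, the remaining factors held at a fixed coded level.
#' Corners are enumerated in Gray-code order (successive corners flip one
#' factor), and the reported best corner is the argmax of the predictions
#' with ties broken by enumeration order.
#'
#' @param model an `"svr_model"` trained on coded settings.
#' @param subset character or integer vector choosing `k` of the model's
#'   factors.
#' @param held_level coded level for the factors outside `subset`;
#'   default `-1` (the leaner medium).
#' @return A data frame of class `"corner_report"` with the `2^k` coded
#'   assignments, natural-unit columns (when the model has a factor
#'   table, named `<factor>_nat`), and `.pred`; attribute `best` holds the
#'   argmax row index.
#' @examples
#' scr <- cho_screen()
#' fit <- svr_fit(scr$design$coded, scr$response, C = 2, gamma = 0.05,
#'                factors = scr$design$factors)
#' corner_predictions(fit, c("X1", "X4", "X5"))
#' @export
corner_predictions <- function(model, subset, held_level = -1) {
  stopifnot(inherits(model, "svr_model"))
  m <- ncol(model$X)
  nms <- colnames(model$X)
  if (is.null(nms)) nms <- paste0("X", seq_len(m))
  idx <- if (is.character(subset)) match(subset, nms) else as.integer(subset)
  if (anyNA(idx) || any(idx < 1) || any(idx > m) || anyDuplicated(idx)) {
    stop("subset must select distinct factors of the model")
  }
  k <- length(idx)
  corners <- .gray_corners(k)
  X <- matrix(held_level, nrow(corners), m, dimnames = list(NULL, nms))
  X[, idx] <- corners
  pred <- predict(model, X)
  out <- as.data.frame(corners)
  names(out) <- nms[idx]
  if (!is.null(model$factors)) {
    nat <- decode_levels(X, model$factors)[, idx, drop = FALSE]
    colnames(nat) <- paste0(nms[idx], "_nat")
    out <- cbind(out, nat)
  }
  out$.pred <- pred
  best <- which.max(pred)        # which.max takes the first maximum: tie
                                 # break = enumeration order
  structure(out, best = best, class = c("corner_report", "data.frame"))
}

#' Prediction grid over two factors
#'
#' Evaluates the surrogate over a regular `resolution x resolution` grid
#' of the coded range `[-1, 1]^2` of two chosen factors, the others held
#' fixed; the result is contour-ready. Rows index `factor_a`, columns
#' `factor_b`; dimnames carry the coded coordinates.
#'
#' @inheritParams corner_predictions
#' @param factor_a,factor_b factor names or indices of the two axes.
#' @param resolution grid points per axis, `>= 2`.
#' @return A numeric matrix with attributes `a` and `b` (axis coordinate
#'   vectors).
#' @export
grid_predictions <- function(model, factor_a, factor_b, resolution = 21,
                             held_level = -1) {
  stopifnot(inherits(model, "svr_model"), resolution >= 2)
  m <- ncol(model$X)
  nms <- colnames(model$X)
  if (is.null(nms)) nms <- paste0("X", seq_len(m))
  ia <- if (is.character(factor_a)) match(factor_a, nms) else as.integer(factor_a)
  ib <- if (is.character(factor_b)) match(factor_b, nms) else as.integer(factor_b)
  if (anyNA(c(ia, ib)) || ia == ib) stop("factor_a and factor_b must be distinct factors")
  s <- seq(-1, 1, length.out = resolution)
  g <- expand.grid(a = s, b = s)
  X <- matrix(held_level, nrow(g), m, dimnames = list(NULL, nms))
  X[, ia] <- g$a; X[, ib] <- g$b
  pred <- matrix(predict(model, X), resolution, resolution,
                 dimnames = list(format(s, trim = TRUE),
                                 format(s, trim = TRUE)))
  attr(pred, "a") <- s; attr(pred, "b") <- s
  attr(pred, "axes") <- c(a = nms[ia], b = nms[ib])
  pred
}

#' Predict at proportionally expanded supplement levels
#'
#' Rescales the natural-unit settings of given runs by a common factor
#' (e.g. 1.5 for "one-and-a-half-times supplements"), re-encodes them
#' through the model's scaling and predicts. Settings outside the trained
#' coded range `[-1, 1]` are extrapolations of the surrogate and trigger a
#' warning; far from the data an RBF model decays to its bias `b`, so
#' extrapolated values should be read qualitatively only.
#'
#' @param model an `"svr_model"` with a factor table.
#' @param scale positive level multiplier.
#' @param X_natural natural-unit matrix of runs to rescale; defaults to
#'   the decoded training runs.
#' @return A data frame with the scaled settings, `.pred`, and a logical
#'   `.extrapolated` column.
#' @export
predict_expanded_levels <- function(model, scale = 1.5, X_natural = NULL) {
  stopifnot(inherits(model, "svr_model"), scale > 0)
  if (is.null(model$factors)) stop("model carries no factor table")
  if (is.null(X_natural)) X_natural <- decode_levels(model$X, model$factors)
  X_scaled <- as.matrix(X_natural) * scale
  coded <- encode_levels(X_scaled, model$factors, snap = FALSE)
  extra <- apply(coded, 1, function(r) any(r < -1 - 1e-9 | r > 1 + 1e-9))
  if (any(extra)) {
    warning(sum(extra), " run(s) fall outside the trained level range; ",
            "predictions there are extrapolations")
  }
  out <- as.data.frame(X_scaled)
  out$.pred <- predict(model, coded)
  out$.extrapolated <- extra
  out
}

#' @export
print.corner_report <- function(x, ...) {
  cat("Corner predictions (Gray-code order); best corner: row ",
      attr(x, "best"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
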