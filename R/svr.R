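#' Radial-basis-function kernel
#'
#' `K(u, v) = exp(-gamma * ||u - v||^2)`. Values lie in `(0, 1]` and
#' `K(u, u) = 1`.
#'
#' @param u,v numeric vectors of equal length, or matrices with points in
#'   rows (then the full cross-kernel matrix is returned).
#' @param gamma kernel width, `> 0`; larger values make the kernel more
#'   local.
#' @return A similarity value, or an `nrow(u)` by `nrow(v)` matrix.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = log(2))  # 0.5
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  if (is.matrix(u) || is.matrix(v)) {
    u <- as.matrix(u); v <- as.matrix(v)
    if (ncol(u) != ncol(v)) {
      stop("dimension mismatch: ", ncol(u), " vs ", ncol(v), " columns")
    }
    d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * tcrossprod(u, v)
    exp(-gamma * pmax(d2, 0))
  } else {
    if (length(u) != length(v)) {
      stop("dimension mismatch: ", length(u), " vs ", length(v))
    }
    exp(-gamma * sum((u - v)^2))
  }
}

#' Train an epsilon-SVR by sequential minimal optimization
#'
#' Solves the dual of epsilon-insensitive support vector regression with
#' an RBF kernel: minimise
#' `1/2 (a - a*)' Q (a - a*) + epsilon * sum(a + a*) - y'(a* - a)` subject
#' to `sum(a* - a) = 0` and `0 <= a, a* <= C`, where `Q_ij = K(x_i, x_j)`.
#' The fitted function is `f(x) = sum_i beta_i K(x, x_i) + b` with
#' `beta_i = a*_i - a_i`. Residuals smaller than `epsilon` are not
#' penalised (the "tube"); `C` bounds each `|beta_i|` and trades data
#' fidelity against flatness.
#'
#' The solver repeatedly optimises the maximal-KKT-violating pair of dual
#' variables in closed form (ties broken by lowest index), stopping when
#' the KKT gap falls below `tol`. The bias is the mean of the KKT
#' estimates over unbounded support vectors, or the midpoint of the
#' feasible interval when every support vector is at bound.
#'
#' @param X numeric matrix of training inputs (rows = samples), in model
#'   space. The screening pipeline trains on coded -1/+1 settings; pass
#'   `factors` so the model can encode natural-unit inputs at prediction
#'   time.
#' @param y numeric response vector.
#' @param C regularisation constant, `> 0`.
#' @param gamma RBF kernel width, `> 0`.
#' @param epsilon tube half-width, `>= 0`. Default 0.01 (d^-1): an order
#'   of magnitude below the span of the packaged screen's growth rates, so
#'   the surrogate can follow the data closely without interpolating
#'   noise exactly.
#' @param tol KKT convergence tolerance of the solver.
#' @param max_iter iteration cap; default `max(1000, 10 * n^2)`, hard cap
#'   100000. Non-convergence is an error reporting the residual KKT gap.
#' @param factors optional [factor_table()] describing the columns of `X`,
#'   enabling `units = "natural"` prediction.
#' @return An object of class `"svr_model"`: list with `X`, `beta`, `b`,
#'   `C`, `gamma`, `epsilon`, `objective` (optimal dual objective),
#'   `iterations`, `factors`.
#' @examples
#' scr <- cho_screen()
#' fit <- svr_fit(scr$design$coded, scr$response, C = 2.3677, gamma = 91.9133)
#' r_squared(predict(fit, scr$design$coded), scr$response)
#' @export
svr_fit <- function(X, y, C, gamma, epsilon = 0.01, tol = 1e-6,
                    max_iter = NULL, factors = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 1) stop("need at least one training sample")
  if (length(y) != n) stop("X and y dimensions disagree")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("inputs must be finite")
  if (C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be non-negative")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(max_iter)) max_iter <- min(max(1000L, 10L * n^2), 100000L)

  K <- rbf_kernel(X, X, gamma)
  sol <- .smo_solve(K, y, C, epsilon, tol, max_iter)
  structure(list(X = X, beta = sol$beta, b = sol$b, C = C, gamma = gamma,
                 epsilon = epsilon, objective = sol$objective,
                 iterations = sol$iterations, factors = factors),
            class = "svr_model")
}

# SMO on the 2n-variable dual: u = [a*; a], s = [+1...; -1...],
# constraint sum(s * u) = 0, box [0, C]. beta = a* - a.
.smo_solve <- function(K, y, C, epsilon, tol, max_iter) {
  n <- length(y)
  u <- numeric(2L * n)
  s <- rep(c(1, -1), each = n)
  idx <- rep(seq_len(n), 2L)
  beta <- numeric(n)
  Kb <- numeric(n)              # K %*% beta, maintained incrementally
  eps_bound <- 1e-12 * max(C, 1)
  it <- 0L
  repeat {
    sg <- s * (s * (Kb[idx] - y[idx]) + epsilon)   # s_t * G_t
    up   <- (s > 0 & u < C - eps_bound) | (s < 0 & u > eps_bound)
    down <- (s > 0 & u > eps_bound)     | (s < 0 & u < C - eps_bound)
    if (!any(up) || !any(down)) break
    t_i <- which(up)[which.min(sg[up])]
    r_i <- which(down)[which.max(sg[down])]
    gap <- sg[r_i] - sg[t_i]
    if (gap <= tol) break
    it <- it + 1L
    if (it > max_iter) {
      stop(sprintf(paste0("SMO did not converge in %d iterations ",
                          "(KKT gap %.3e > tol %.1e)"), max_iter, gap, tol))
    }
    a <- idx[t_i]; b2 <- idx[r_i]
    kappa <- K[a, a] + K[b2, b2] - 2 * K[a, b2]
    rho <- sg[t_i] - sg[r_i]
    lim <- function(tt, sgn) {        # bounds on step h from u[tt] in [0, C]
      if (sgn * s[tt] > 0) c(-u[tt], C - u[tt]) else c(u[tt] - C, u[tt])
    }
    l1 <- lim(t_i, 1); l2 <- lim(r_i, -1)
    lo <- max(l1[1], l2[1]); hi <- min(l1[2], l2[2])
    h <- if (kappa > 1e-12) -rho / kappa else if (rho < 0) hi else lo
    h <- min(max(h, lo), hi)
    if (abs(h) < 1e-15) break
    u[t_i] <- min(max(u[t_i] + s[t_i] * h, 0), C)
    u[r_i] <- min(max(u[r_i] - s[r_i] * h, 0), C)
    if (a != b2) {
      beta[a] <- beta[a] + h
      beta[b2] <- beta[b2] - h
      Kb <- Kb + h * (K[, a] - K[, b2])
    }
  }
  sg <- s * (s * (Kb[idx] - y[idx]) + epsilon)
  free <- u > 1e-8 * C & u < C * (1 - 1e-8)
  b <- if (any(free)) {
    mean(-sg[free])
  } else {
    up   <- (s > 0 & u < C - eps_bound) | (s < 0 & u > eps_bound)
    down <- (s > 0 & u > eps_bound)     | (s < 0 & u < C - eps_bound)
    lo <- if (any(up)) min(sg[up]) else -Inf
    hi <- if (any(down)) max(sg[down]) else Inf
    if (is.finite(lo) && is.finite(hi)) -(lo + hi) / 2 else 0
  }
  objective <- 0.5 * sum(beta * Kb) + epsilon * sum(u) - sum(y * beta)
  list(beta = beta, b = b, objective = objective, iterations = it)
}

#' Predict from a fitted epsilon-SVR
#'
#' Evaluates `f(x) = sum_i beta_i K(x, x_i) + b`.
#'
#' @param object an `"svr_model"`.
#' @param newdata matrix (or vector) of inputs; columns must match the
#'   training dimension.
#' @param units `"model"` (default): `newdata` is already in the space the
#'   model was trained on; `"natural"`: `newdata` holds natural-unit
#'   concentrations and is encoded through the model's factor table first.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, units = c("model", "natural"),
                              ...) {
  units <- match.arg(units)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (units == "natural") {
    if (is.null(object$factors)) {
      stop("model carries no factor table; cannot encode natural units")
    }
    newdata <- encode_levels(newdata, object$factors, snap = FALSE)
  }
  if (ncol(newdata) != ncol(object$X)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         ncol(object$X))
  }
  drop(rbf_kernel(newdata, object$X, object$gamma) %*% object$beta + object$b)
}

#' @export
print.svr_model <- function(x, ...) {
  nsv <- sum(abs(x$beta) > 1e-10)
  cat("epsilon-SVR (RBF kernel)\n",
      "  n = ", length(x$beta), ", support vectors = ", nsv, "\n",
      "  C = ", format(x$C), ", gamma = ", format(x$gamma),
      ", epsilon = ", format(x$epsilon), "\n",
      "  bias b = ", format(x$b), ", dual objective = ",
      format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Fit-quality metrics
#'
#' `mse_half()` is the squared-error loss in the convention usual in the
#' SVM literature: one-half the *sum* of squared residuals,
#' `1/2 * sum((f - y)^2)` -- note, not the mean. `r_squared()` is the
#' conventional coefficient of determination `1 - SS_res / SS_tot`.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return A single number. `r_squared()` errors when the observed
#'   response has zero variance.
#' @examples
#' mse_half(c(1, 2), c(1.1, 1.9))   # 0.5 * (0.01 + 0.01)
#' @export
mse_half <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  0.5 * sum((predicted - observed)^2)
}

#' @rdname mse_half
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least two observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed response is constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Leave-one-out cross-validated squared error
#'
#' Mean over samples of the squared error made when predicting each sample
#' from a model trained on the remaining `n - 1`. With only 12 runs this
#' is the natural estimate of out-of-sample error and is the default
#' fitness of the hyperparameter search.
#'
#' @inheritParams svr_fit
#' @return Mean squared leave-one-out prediction error.
#' @export
loo_cv_mse <- function(X, y, C, gamma, epsilon = 0.01, tol = 1e-6) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2) stop("leave-one-out needs at least two samples")
  err2 <- vapply(seq_len(n), function(i) {
    fit <- svr_fit(X[-i, , drop = FALSE], y[-i], C = C, gamma = gamma,
                   epsilon = epsilon, tol = tol)
    (predict(fit, X[i, , drop = FALSE]) - y[i])^2
  }, numeric(1))
  mean(err2)
}

#' Serialize an SVR model to JSON and back
#'
#' Numbers are written with 17 significant digits, so the round-trip is
#' bit-exact for double precision.
#'
#' @param model an `"svr_model"`.
#' @param path JSON file path.
#' @return `svr_to_json()` the path invisibly; `svr_from_json()` the
#'   model.
#' @export
svr_to_json <- function(model, path) {
  stopifnot(inherits(model, "svr_model"))
  doc <- list(
    type = "svr_model", kernel = "rbf",
    C = model$C, gamma = model$gamma, epsilon = model$epsilon,
    b = model$b, beta = model$beta, X = model$X,
    objective = model$objective, iterations = model$iterations
  )
  if (!is.null(model$factors)) {
    doc$factors <- as.data.frame(unclass(model$factors))
  }
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svr_to_json
#' @export
svr_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || doc$type != "svr_model") {
    stop(path, " does not contain an svr_model document")
  }
  factors <- NULL
  if (!is.null(doc$factors) && length(doc$factors)) {
    f <- as.data.frame(doc$factors, stringsAsFactors = FALSE)
    factors <- factor_table(name = f$name, low = f$low, high = f$high,
                            units = f$units, label = f$label)
  }
  structure(list(X = as.matrix(doc$X), beta = as.numeric(doc$beta),
                 b = doc$b, C = doc$C, gamma = doc$gamma,
                 epsilon = doc$epsilon, objective = doc$objective,
                 iterations = doc$iterations, factors = factors),
            class = "svr_model")
}
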