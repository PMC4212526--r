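# Shared helpers: independent oracles and small random problem generators.

# Decimal half-up rounding, the convention of the published tables (R's
# round() is half-even). The 1e-9 slack absorbs binary representation
# error of exact decimal halves such as 0.2305.
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

# Published 12-run screen, used throughout.
fixture_screen <- function() cho_screen()

# Random small epsilon-SVR instance (for solver cross-checks).
random_svr_instance <- function(n_max = 20) {
  n <- sample(4:n_max, 1)
  m <- sample(2:6, 1)
  list(
    X = matrix(stats::rnorm(n * m), n),
    y = stats::rnorm(n),
    C = exp(stats::runif(1, log(0.1), log(50))),
    gamma = exp(stats::runif(1, log(0.05), log(5))),
    epsilon = stats::runif(1, 0, 0.2)
  )
}

# Generic interior-point QP solve of the epsilon-SVR dual via kernlab::ipop,
# on the 2n-variable box formulation u = [alpha*; alpha]. Returns the dual
# objective in the same convention as svr_fit()$objective, or NULL when the
# interior-point method fails to converge on that instance.
qp_dual_objective <- function(inst) {
  K <- rbf_kernel(inst$X, inst$X, inst$gamma)
  n <- length(inst$y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * n)
  cvec <- c(inst$epsilon - inst$y, inst$epsilon + inst$y)
  qp <- try(kernlab::ipop(
    c = matrix(cvec), H = H,
    A = matrix(rep(c(1, -1), each = n), 1), b = 0,
    l = matrix(rep(0, 2 * n)), u = matrix(rep(inst$C, 2 * n)), r = 0,
    sigf = 9, maxiter = 80), silent = TRUE)
  if (inherits(qp, "try-error")) return(NULL)
  u <- kernlab::primal(qp)
  beta <- u[1:n] - u[(n + 1):(2 * n)]
  0.5 * sum(beta * (K %*% beta)) + inst$epsilon * sum(u) - sum(inst$y * beta)
}

# Reference LIBSVM fit (tight tolerance) for prediction cross-checks.
libsvm_predictions <- function(inst, newdata = inst$X) {
  fit <- e1071::svm(inst$X, inst$y, type = "eps-regression",
                    kernel = "radial", cost = inst$C, gamma = inst$gamma,
                    epsilon = inst$epsilon, scale = FALSE,
                    tolerance = 1e-8)
  as.numeric(stats::predict(fit, newdata))
}

# A small balanced orthogonal design with random column signs/permutation,
# for property tests that should not depend on the fixture layout.
random_pb12 <- function() {
  d <- pb_design(12, 7)
  cols <- sample(7)
  signs <- sample(c(-1, 1), 7, replace = TRUE)
  screen_design(sweep(d$coded[sample(12), cols], 2, signs, "*"))
}
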