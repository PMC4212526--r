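test_that("the RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 4), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = log(2)), 0.5)
  set.seed(11)
  for (i in 1:20) {
    u <- stats::rnorm(5); v <- stats::rnorm(5); g <- stats::runif(1, 0.1, 3)
    expect_equal(rbf_kernel(u, v, g), exp(-g * sum((u - v)^2)),
                 tolerance = 1e-12)
    expect_equal(rbf_kernel(u, v, g), rbf_kernel(v, u, g))
  }
  K <- rbf_kernel(matrix(stats::rnorm(12), 4), matrix(stats::rnorm(9), 3), 0.5)
  expect_identical(dim(K), c(4L, 3L))
  expect_true(all(K > 0 & K <= 1))
  expect_error(rbf_kernel(1:3, 1:4, 1), "mismatch")
  expect_error(rbf_kernel(1:3, 1:3, -1), "positive")
})

test_that("constant responses yield the flat model inside the tube", {
  X <- matrix(stats::rnorm(20), 5)
  fit <- svr_fit(X, rep(0.27, 5), C = 10, gamma = 1)
  expect_equal(fit$beta, rep(0, 5))
  expect_equal(fit$b, 0.27)
  expect_equal(predict(fit, matrix(stats::rnorm(8), 2)), rep(0.27, 2))
})

test_that("a single training point is fitted within the tube", {
  fit <- svr_fit(matrix(c(1, 2), 1), 0.3, C = 5, gamma = 0.5, epsilon = 0.01)
  expect_lte(abs(predict(fit, c(1, 2)) - 0.3), 0.01 + 1e-8)
})

test_that("predictions are the kernel expansion over support coefficients", {
  # hand-evaluated 3-point expansion
  model <- structure(list(
    X = matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE),
    beta = c(0.5, -0.2, 0.1), b = 0.05, C = 1, gamma = 2, epsilon = 0.1,
    objective = NA_real_, iterations = 0L, factors = NULL),
    class = "svr_model")
  xs <- matrix(stats::rnorm(10), 5)
  direct <- apply(xs, 1, function(x) {
    s <- 0
    for (i in 1:3) s <- s + model$beta[i] * exp(-2 * sum((x - model$X[i, ])^2))
    s + 0.05
  })
  expect_equal(predict(model, xs), direct, tolerance = 1e-12)
  expect_error(predict(model, matrix(1, 1, 3)), "columns")
  # all-zero coefficients predict the bias everywhere
  model$beta <- rep(0, 3); model$b <- 0.2
  expect_equal(predict(model, xs), rep(0.2, 5))
})

test_that("the SMO solution is dual feasible and satisfies the KKT geometry", {
  set.seed(101)
  for (i in 1:10) {
    inst <- random_svr_instance()
    fit <- svr_fit(inst$X, inst$y, C = inst$C, gamma = inst$gamma,
                   epsilon = inst$epsilon, tol = 1e-8)
    expect_lt(abs(sum(fit$beta)), 1e-8)
    expect_true(all(abs(fit$beta) <= inst$C + 1e-12))
    # unbounded support vectors sit on the tube boundary
    resid <- predict(fit, inst$X) - inst$y
    free <- abs(fit$beta) > 1e-6 * inst$C &
      abs(fit$beta) < inst$C * (1 - 1e-6)
    if (any(free)) {
      expect_lt(max(abs(abs(resid[free]) - inst$epsilon)), 1e-5)
    }
    # zero-coefficient samples lie inside the tube
    inside <- abs(fit$beta) < 1e-10
    if (any(inside)) {
      expect_true(all(abs(resid[inside]) <= inst$epsilon + 1e-6))
    }
  }
})

test_that("SMO matches the interior-point QP oracle and LIBSVM", {
  set.seed(202)
  solved <- 0
  while (solved < 10) {
    inst <- random_svr_instance()
    fit <- svr_fit(inst$X, inst$y, C = inst$C, gamma = inst$gamma,
                   epsilon = inst$epsilon, tol = 1e-8)
    obj_qp <- qp_dual_objective(inst)
    if (!is.null(obj_qp)) {
      solved <- solved + 1
      expect_lt(abs(fit$objective - obj_qp), 1e-6)
    }
    expect_equal(predict(fit, inst$X), libsvm_predictions(inst),
                 tolerance = 1e-4)
  }
})

test_that("the optimal dual objective is monotone in C", {
  scr <- fixture_screen()
  objs <- vapply(c(0.1, 0.5, 2, 10, 50), function(C) {
    svr_fit(scr$design$coded, scr$response, C = C, gamma = 0.1)$objective
  }, numeric(1))
  # larger C enlarges the feasible box, so the minimum can only decrease
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("the model interpolates distinct points as the tube vanishes", {
  scr <- fixture_screen()
  fit <- svr_fit(scr$design$coded, scr$response, C = 1e4, gamma = 50,
                 epsilon = 1e-4)
  resid <- predict(fit, scr$design$coded) - scr$response
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("fit metrics follow their definitions", {
  expect_equal(mse_half(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # constant residual r over n points: half-sum is n r^2 / 2
  n <- 7; r <- 0.3
  y <- stats::rnorm(n)
  expect_equal(mse_half(y + r, y), n * r^2 / 2, tolerance = 1e-12)
  set.seed(5)
  p <- stats::rnorm(10); o <- stats::rnorm(10)
  expect_equal(mse_half(p, o), 0.5 * sum((p - o)^2), tolerance = 1e-12)
  expect_equal(r_squared(p, o), 1 - sum((o - p)^2) / sum((o - mean(o))^2),
               tolerance = 1e-12)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
  expect_error(mse_half(1:3, 1:4), "mismatch")
})

test_that("leave-one-out error matches an explicit fold loop", {
  scr <- fixture_screen()
  X <- scr$design$coded[1:6, ]; y <- scr$response[1:6]
  got <- loo_cv_mse(X, y, C = 2, gamma = 0.1)
  manual <- mean(vapply(1:6, function(i) {
    f <- svr_fit(X[-i, , drop = FALSE], y[-i], C = 2, gamma = 0.1)
    (predict(f, X[i, , drop = FALSE]) - y[i])^2
  }, numeric(1)))
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(loo_cv_mse(X, rep(0.2, 6), C = 2, gamma = 0.1), 0)

  # n = 2, zero tube: each fold predicts the other point's value
  X2 <- matrix(c(0, 1), 2, 1)
  y2 <- c(0.1, 0.3)
  expect_equal(loo_cv_mse(X2, y2, C = 10, gamma = 1, epsilon = 0),
               (0.1 - 0.3)^2, tolerance = 1e-9)
})

test_that("models serialize to JSON and back without loss", {
  scr <- fixture_screen()
  fit <- svr_fit(scr$design$coded, scr$response, C = 2.3677, gamma = 91.9133,
                 factors = scr$design$factors)
  tmp <- withr::local_tempfile(fileext = ".json")
  svr_to_json(fit, tmp)
  back <- svr_from_json(tmp)
  expect_identical(back$beta, fit$beta)
  expect_identical(back$b, fit$b)
  expect_identical(back$gamma, fit$gamma)
  expect_identical(unname(back$X), unname(fit$X))
  grid <- matrix(stats::runif(21, -1, 1), 3)
  expect_identical(predict(back, grid), unname(predict(fit, grid)))
  expect_equal(as.data.frame(back$factors), as.data.frame(fit$factors))
})
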