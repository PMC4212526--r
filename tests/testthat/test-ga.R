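quad_fitness <- function(p) (p[["C"]] - 10)^2 + (p[["gamma"]] - 5)^2

test_that("the GA is deterministic under a fixed seed", {
  ctl <- ga_control(generations = 30, seed = 99,
                    upper = c(C = 100, gamma = 100))
  r1 <- run_ga(quad_fitness, ctl)
  r2 <- run_ga(quad_fitness, ctl)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("elitism makes the best-so-far trajectory non-increasing", {
  for (seed in c(1, 7, 20140101)) {
    r <- run_ga(quad_fitness,
                ga_control(generations = 40, seed = seed,
                           upper = c(C = 100, gamma = 100)))
    expect_true(all(diff(r$trajectory$best_fitness) <= 0))
    expect_equal(r$value, min(r$trajectory$best_fitness))
  }
})

test_that("every evaluated individual respects the box bounds", {
  seen <- NULL
  probe <- function(p) {
    seen <<- rbind(seen, p)
    quad_fitness(p)
  }
  ctl <- ga_control(generations = 15, seed = 3,
                    lower = c(C = 0.5, gamma = 0.2),
                    upper = c(C = 20, gamma = 50))
  run_ga(probe, ctl)
  expect_true(all(seen[, 1] >= 0.5 & seen[, 1] <= 20))
  expect_true(all(seen[, 2] >= 0.2 & seen[, 2] <= 50))
})

test_that("one generation with full elitism returns the initial best", {
  ctl <- ga_control(pop_size = 10, generations = 1, elitism = 10, seed = 42)
  r <- run_ga(quad_fitness, ctl)
  # reproduce the initial population ourselves (log-scale sampling)
  set.seed(42)
  lower <- log(ctl$lower); upper <- log(ctl$upper)
  pop <- sapply(1:2, function(j) stats::runif(10, lower[j], upper[j]))
  fits <- apply(exp(pop), 1, function(p) quad_fitness(c(C = p[1], gamma = p[2])))
  expect_equal(r$value, min(fits))
})

test_that("non-finite fitness values are quarantined, not fatal", {
  spiky <- function(p) if (p[["C"]] > 50) NaN else quad_fitness(p)
  expect_message(
    r <- run_ga(spiky, ga_control(generations = 10, seed = 8,
                                  upper = c(C = 100, gamma = 100))),
    "non-finite")
  expect_true(is.finite(r$value))
  expect_lte(r$par[["C"]], 50)
})

test_that("GA configs are validated", {
  expect_error(ga_control(pop_size = 1), "pop_size")
  expect_error(ga_control(lower = c(C = -1, gamma = 0.01)), "positive")
  expect_error(ga_control(crossover_prob = 1.2), "crossover_prob")
})

test_that("SVR tuning returns a refitted model and honours fixed bounds", {
  scr <- fixture_screen()
  ctl <- ga_control(pop_size = 8, generations = 5, seed = 13)
  res <- svr_tune(scr$design$coded, scr$response, control = ctl,
                  factors = scr$design$factors)
  expect_s3_class(res$model, "svr_model")
  expect_equal(res$model$C, res$par[["C"]])
  expect_true(res$par[["C"]] >= 0.01 && res$par[["C"]] <= 100)
  expect_true(res$par[["gamma"]] >= 0.01 && res$par[["gamma"]] <= 1000)
  # fitness of the winner is reproducible
  expect_equal(loo_cv_mse(scr$design$coded, scr$response,
                          C = res$par[["C"]], gamma = res$par[["gamma"]]),
               res$value, tolerance = 1e-12)
  # constant response: any parameter pair attains zero fitness
  res0 <- svr_tune(scr$design$coded, rep(0.2, 12), control = ctl)
  expect_equal(res0$value, 0)
  # training-error fitness is available and favours tight fits
  rest <- svr_tune(scr$design$coded, scr$response, control = ctl,
                   fitness = "train")
  expect_s3_class(rest$model, "svr_model")
})

test_that("tuning traces are written as CSV", {
  r <- run_ga(quad_fitness, ga_control(generations = 5, seed = 2,
                                       upper = c(C = 100, gamma = 100)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_ga_trace_csv(r, tmp)
  tr <- utils::read.csv(tmp)
  expect_identical(nrow(tr), 5L)
  expect_named(tr, c("generation", "best_fitness", "C", "gamma"))
})
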