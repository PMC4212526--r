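#' Genetic-algorithm settings
#'
#' Real-coded GA with tournament selection (size 2), arithmetic (blend)
#' crossover, Gaussian mutation (per-gene sd = 10% of the box width,
#' clipped to the box) and elitism. Defaults follow the shipped case
#' study's search: population 20, 200 generations, over
#' `C` in `[0.01, 100]` and `gamma` in `[0.01, 1000]`.
#'
#' @param pop_size population size, `>= 2`.
#' @param generations number of generations, `>= 1`.
#' @param crossover_prob,mutation_prob operator probabilities in `[0, 1]`.
#' @param lower,upper named numeric vectors bounding the search box;
#'   positive with `lower < upper`.
#' @param elitism number of best individuals copied unchanged into the
#'   next generation; with `elitism >= 1` the best-so-far fitness is
#'   non-increasing.
#' @param scale `"log"` (default) applies all GA operators in log
#'   coordinates, the appropriate metric for scale parameters such as `C`
#'   and `gamma` whose plausible values span several decades; `"linear"`
#'   works on the raw box. Fitness is always evaluated on natural
#'   parameters.
#' @param seed RNG seed making the search reproducible bit-for-bit.
#' @return A list of class `"ga_control"`.
#' @export
ga_control <- function(pop_size = 20, generations = 200,
                       crossover_prob = 0.7, mutation_prob = 0.1,
                       lower = c(C = 0.01, gamma = 0.01),
                       upper = c(C = 100, gamma = 1000),
                       elitism = 1, scale = c("log", "linear"),
                       seed = 20140101) {
  scale <- match.arg(scale)
  stopifnot(pop_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism >= 0, elitism <= pop_size,
            length(lower) == length(upper))
  if (any(lower <= 0) || any(lower >= upper)) {
    stop("bounds must be positive with lower < upper")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 lower = lower, upper = upper,
                 elitism = as.integer(elitism), scale = scale, seed = seed),
            class = "ga_control")
}

#' Minimise a fitness function with a genetic algorithm
#'
#' Generational GA over a box: tournament selection of parents, blend
#' crossover (`child = lambda * p1 + (1 - lambda) * p2`, `lambda ~ U(0,1)`
#' per gene), Gaussian mutation clipped to the box, elitism. Non-finite
#' fitness values are treated as `+Inf` (with a message), never an error.
#'
#' @param fitness function taking a named numeric parameter vector and
#'   returning a single number to be minimised.
#' @param control a [ga_control()].
#' @return A list of class `"ga_result"`: `par` (best-ever parameters),
#'   `value` (its fitness), `trajectory` (data frame per generation:
#'   `generation`, `best_fitness`, one column per parameter of the
#'   best-so-far individual).
#' @examples
#' res <- run_ga(function(p) (p["C"] - 10)^2 + (p["gamma"] - 5)^2,
#'               ga_control(upper = c(C = 100, gamma = 100)))
#' res$par
#' @export
run_ga <- function(fitness, control = ga_control()) {
  stopifnot(inherits(control, "ga_control"))
  d <- length(control$lower)
  nm <- names(control$lower)
  to_nat <- if (control$scale == "log") exp else identity
  lower <- if (control$scale == "log") log(control$lower) else control$lower
  upper <- if (control$scale == "log") log(control$upper) else control$upper
  width <- upper - lower
  if (!is.null(control$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(control$seed)
  }
  evaluate <- function(p) {
    v <- fitness(stats::setNames(to_nat(p), nm))
    if (!is.finite(v)) {
      message("non-finite fitness at (", paste(signif(p, 6), collapse = ", "),
              "); treated as +Inf")
      v <- Inf
    }
    v
  }
  pop <- sapply(seq_len(d), function(j) {
    stats::runif(control$pop_size, lower[j], upper[j])
  })
  pop <- matrix(pop, nrow = control$pop_size)
  fit <- apply(pop, 1, evaluate)
  best_i <- which.min(fit)
  best <- pop[best_i, ]; best_fit <- fit[best_i]
  traj <- matrix(NA_real_, control$generations, d)
  traj_fit <- numeric(control$generations)

  mutate <- function(x) {
    hit <- stats::runif(d) < control$mutation_prob
    if (any(hit)) {
      x[hit] <- x[hit] + stats::rnorm(sum(hit), 0, 0.1 * width[hit])
    }
    pmin(pmax(x, lower), upper)
  }
  tournament <- function() {
    a <- sample.int(control$pop_size, 2)
    if (fit[a[1]] <= fit[a[2]]) pop[a[1], ] else pop[a[2], ]
  }
  for (g in seq_len(control$generations)) {
    newpop <- matrix(NA_real_, control$pop_size, d)
    if (control$elitism > 0) {
      keep <- order(fit)[seq_len(control$elitism)]
      newpop[seq_len(control$elitism), ] <- pop[keep, , drop = FALSE]
    }
    i <- control$elitism
    while (i < control$pop_size) {
      p1 <- tournament(); p2 <- tournament()
      if (stats::runif(1) < control$crossover_prob) {
        lam <- stats::runif(d)
        c1 <- lam * p1 + (1 - lam) * p2
        c2 <- lam * p2 + (1 - lam) * p1
      } else {
        c1 <- p1; c2 <- p2
      }
      i <- i + 1L; newpop[i, ] <- mutate(c1)
      if (i < control$pop_size) { i <- i + 1L; newpop[i, ] <- mutate(c2) }
    }
    pop <- newpop
    fit <- apply(pop, 1, evaluate)
    gi <- which.min(fit)
    if (fit[gi] < best_fit) { best_fit <- fit[gi]; best <- pop[gi, ] }
    traj[g, ] <- to_nat(best)
    traj_fit[g] <- best_fit
  }
  trajectory <- data.frame(generation = seq_len(control$generations),
                           best_fitness = traj_fit)
  trajectory[nm] <- traj
  structure(list(par = stats::setNames(to_nat(best), nm), value = best_fit,
                 trajectory = trajectory, control = control),
            class = "ga_result")
}

#' Tune SVR hyperparameters (C, gamma) by GA
#'
#' Searches the `(C, gamma)` box minimising either the leave-one-out
#' cross-validated mean squared error (default; the honest out-of-sample
#' criterion for a 12-run screen) or the training squared-error loss
#' ([mse_half()]), which favours near-interpolating large-`gamma` models.
#'
#' @inheritParams svr_fit
#' @param control a [ga_control()].
#' @param fitness `"loo"` (default) or `"train"`.
#' @return A `"ga_result"` (see [run_ga()]) with an extra element `model`:
#'   the SVR refitted on all data at the best `(C, gamma)`.
#' @export
svr_tune <- function(X, y, epsilon = 0.01, control = ga_control(),
                     fitness = c("loo", "train"), factors = NULL) {
  fitness <- match.arg(fitness)
  X <- as.matrix(X); y <- as.numeric(y)
  fn <- if (fitness == "loo") {
    function(p) loo_cv_mse(X, y, C = p[["C"]], gamma = p[["gamma"]],
                           epsilon = epsilon)
  } else {
    function(p) {
      fit <- svr_fit(X, y, C = p[["C"]], gamma = p[["gamma"]],
                     epsilon = epsilon)
      mse_half(predict(fit, X), y)
    }
  }
  res <- run_ga(fn, control)
  res$model <- svr_fit(X, y, C = res$par[["C"]], gamma = res$par[["gamma"]],
                       epsilon = epsilon, factors = factors)
  res$fitness <- fitness
  res
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA search (", x$control$pop_size, " x ", x$control$generations,
      " generations)\n  best: ", sep = "")
  cat(paste(names(x$par), "=", signif(x$par, 6), collapse = ", "),
      "\n  fitness:", format(x$value), "\n")
  invisible(x)
}

#' Write a GA tuning trace as CSV
#'
#' @param result a `"ga_result"`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_ga_trace_csv <- function(result, path) {
  utils::write.csv(result$trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
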