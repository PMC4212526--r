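# Provenance header stamped into every pipeline output file.
.stamp <- function(path, seed, extra = "") {
  ver <- as.character(utils::packageVersion("pbsvr"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# pbsvr %s | seed %s%s", ver, format(seed),
                     if (nzchar(extra)) paste0(" | ", extra) else ""), con)
  close(con)
  path
}

.append_csv <- function(df, path) {
  suppressWarnings(
    utils::write.table(df, path, append = TRUE, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  )
  invisible(path)
}

#' Run the screening analysis end to end
#'
#' Reads (or accepts) a screen, writes range-analysis and ANOVA reports in
#' CSV form and returns the tables. Every output carries a provenance
#' header line (`# pbsvr <version> | seed <seed>`), so re-running with the
#' same inputs reproduces the files byte for byte.
#'
#' @param input a screen CSV path, or a list with `design` and `response`
#'   (as returned by [cho_screen()] / [read_screen_csv()]).
#' @param out_dir output directory, created if missing.
#' @param factors optional [factor_table()] used when `input` is a CSV.
#' @param alpha significance level for the report footer.
#' @param seed recorded in output headers (the screen itself is
#'   deterministic).
#' @return Invisibly, a list with `range`, `anova`, `significant`, and the
#'   written `files`.
#' @export
run_screen <- function(input, out_dir = ".", factors = NULL, alpha = 0.05,
                       seed = 20140101) {
  scr <- if (is.character(input)) {
    read_screen_csv(input, factors = factors)
  } else input
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rng <- range_analysis(scr$design, scr$response)
  av <- pb_anova(scr$design, scr$response)
  sig <- significant_factors(av, alpha)
  f_rng <- file.path(out_dir, "range_analysis.csv")
  f_av <- file.path(out_dir, "anova.csv")
  .stamp(f_rng, seed); .append_csv(as.data.frame(rng), f_rng)
  .stamp(f_av, seed, sprintf("alpha %g | significant: %s", alpha,
                             paste(sig, collapse = " "))
  )
  .append_csv(as.data.frame(av), f_av)
  invisible(list(range = rng, anova = av, significant = sig,
                 files = c(f_rng, f_av)))
}

#' Fit, tune and interrogate the SVR surrogate
#'
#' Trains the epsilon-SVR surrogate on the coded screen (GA-tuned
#' `(C, gamma)` unless both are fixed), computes mean-impact-value
#' importance, and writes the model JSON, the MIV report and (when the GA
#' ran) the tuning trace.
#'
#' @inheritParams run_screen
#' @param epsilon SVR tube half-width.
#' @param fixed_c,fixed_gamma fix both to bypass the GA (e.g. to evaluate
#'   a published parameter pair).
#' @param control [ga_control()] for the tuner; its seed is replaced by
#'   `seed`.
#' @param fitness GA fitness, `"loo"` or `"train"` (see [svr_tune()]).
#' @param delta MIV perturbation fraction.
#' @return Invisibly, a list with `model`, `miv`, `tune` (or `NULL`) and
#'   `files`.
#' @export
run_model <- function(input, out_dir = ".", factors = NULL, epsilon = 0.01,
                      fixed_c = NULL, fixed_gamma = NULL,
                      control = ga_control(), fitness = "loo",
                      delta = 0.10, seed = 20140101) {
  scr <- if (is.character(input)) {
    read_screen_csv(input, factors = factors)
  } else input
  if (is.null(scr$design$factors) && !is.null(factors)) {
    scr$design <- screen_design(scr$design$coded, factors = factors,
                                runs = scr$design$runs)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  tune <- NULL
  if (!is.null(fixed_c) && !is.null(fixed_gamma)) {
    model <- svr_fit(scr$design$coded, scr$response, C = fixed_c,
                     gamma = fixed_gamma, epsilon = epsilon,
                     factors = scr$design$factors)
  } else {
    control$seed <- seed
    tune <- svr_tune(scr$design$coded, scr$response, epsilon = epsilon,
                     control = control, fitness = fitness,
                     factors = scr$design$factors)
    model <- tune$model
    f_trace <- file.path(out_dir, "tuning_trace.csv")
    .stamp(f_trace, seed); .append_csv(tune$trajectory, f_trace)
    files <- c(files, f_trace)
  }
  mv <- miv(model, delta = delta)
  f_model <- file.path(out_dir, "svr_model.json")
  svr_to_json(model, f_model)
  f_miv <- file.path(out_dir, "miv.csv")
  .stamp(f_miv, seed, sprintf("C %.6g | gamma %.6g | epsilon %g | delta %g",
                              model$C, model$gamma, epsilon, delta))
  .append_csv(as.data.frame(mv), f_miv)
  invisible(list(model = model, miv = mv, tune = tune,
                 files = c(files, f_model, f_miv)))
}

#' Explore a fitted surrogate over corners and grids
#'
#' @param model an `"svr_model"` or path to a model JSON.
#' @param subset factor subset for the corner report.
#' @param grid_pair two factors for the 2-D prediction grid.
#' @inheritParams run_screen
#' @inheritParams corner_predictions
#' @param resolution grid points per axis.
#' @return Invisibly, a list with `corners`, `grid` and `files`.
#' @export
run_explore <- function(model, out_dir = ".", subset = c("X1", "X4", "X5"),
                        grid_pair = c("X4", "X5"), held_level = -1,
                        resolution = 21, seed = 20140101) {
  if (is.character(model)) model <- svr_from_json(model)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  corners <- corner_predictions(model, subset, held_level = held_level)
  grd <- grid_predictions(model, grid_pair[1], grid_pair[2],
                          resolution = resolution, held_level = held_level)
  f_corners <- file.path(out_dir, "corners.csv")
  .stamp(f_corners, seed, sprintf("held_level %g | best row %d", held_level,
                                  attr(corners, "best")))
  .append_csv(as.data.frame(corners), f_corners)
  f_grid <- file.path(out_dir, "grid.csv")
  .stamp(f_grid, seed, sprintf("rows %s | cols %s",
                               attr(grd, "axes")[["a"]],
                               attr(grd, "axes")[["b"]]))
  gdf <- data.frame(coded_a = attr(grd, "a"),
                    matrix(grd, nrow(grd), dimnames = dimnames(grd)),
                    check.names = FALSE)
  .append_csv(gdf, f_grid)
  invisible(list(corners = corners, grid = grd, files = c(f_corners, f_grid)))
}

#' Simulate a synthetic screen to CSV
#'
#' @param spec a [synthetic_spec()]; `seed` overrides its seed.
#' @param design a [screen_design()]; default is the 12-run, 7-factor
#'   array.
#' @inheritParams run_screen
#' @return Invisibly, a list with `design`, `response` and `files`.
#' @export
run_simulate <- function(spec, design = pb_design(12, 7), out_dir = ".",
                         seed = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  y <- simulate_response(design, spec)
  f <- file.path(out_dir, "synthetic_screen.csv")
  write_screen_csv(design, y, f)
  invisible(list(design = design, response = y, files = f))
}
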