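#' The packaged 12-run CHO serum-free-medium screen
#'
#' The complete dataset of the shipped case study: a 12-run, 7-factor
#' Plackett-Burman screen of serum-free-medium supplements for suspension
#' CHO-K1 cells, with the specific growth rate (per day, measured after
#' 72 h of culture) as response. Each tabulated response summarises a run
#' performed in triplicate. The run matrix is stored verbatim in its
#' published "Trial" ordering (which is not the cyclic-generator ordering);
#' it passes the balance and orthogonality invariants of
#' [screen_design()].
#'
#' @return A list with elements `design` (a [screen_design()] carrying
#'   [cho_factors()]) and `response` (numeric vector of 12 growth rates,
#'   d^-1).
#' @examples
#' scr <- cho_screen()
#' scr$response[5]   # all-low medium grows slowest
#' @export
cho_screen <- function() {
  coded <- matrix(c(
     1,  1, -1,  1, -1, -1, -1,
    -1,  1,  1,  1, -1,  1,  1,
    -1, -1, -1,  1,  1,  1, -1,
     1, -1,  1,  1, -1,  1, -1,
    -1, -1, -1, -1, -1, -1, -1,
    -1,  1, -1, -1, -1,  1,  1,
    -1,  1,  1, -1,  1, -1, -1,
     1, -1, -1, -1,  1,  1,  1,
     1,  1, -1,  1,  1, -1,  1,
     1,  1,  1, -1,  1,  1, -1,
    -1, -1,  1,  1,  1, -1,  1,
     1, -1,  1, -1, -1, -1,  1), nrow = 12, byrow = TRUE)
  response <- c(0.222, 0.267, 0.282, 0.262, 0.124, 0.102,
                0.217, 0.287, 0.319, 0.251, 0.305, 0.196)
  list(design = screen_design(coded, factors = cho_factors()),
       response = response)
}

#' Read or write a screen table as CSV
#'
#' The CSV dialect has one header row, a run-identifier column, one column
#' per factor and one (or more, see below) response column:
#' `trial,X1,...,X7,growth_rate`. Factor columns may hold either coded
#' levels (exactly the values -1/1) or natural-unit levels, which are
#' auto-detected: a column whose distinct values are `{-1, 1}` is treated
#' as coded, otherwise its values must match the factor's `{low, high}`
#' within relative tolerance `1e-9` and are re-encoded. Anything else is
#' rejected with the offending values listed.
#'
#' If several response columns are given (replicate measurements), they
#' are averaged into one response per run and a note is emitted.
#'
#' @param path CSV file path (UTF-8, `.` decimal separator).
#' @param factors optional [factor_table()]; required to decode
#'   natural-unit factor columns and attached to the returned design.
#' @param run_col,response_col column names; `response_col` may name
#'   several replicate columns. Defaults: first column is the run id, last
#'   column the response.
#' @return `read_screen_csv()`: list with `design` and `response`, as
#'   [cho_screen()].
#' @export
read_screen_csv <- function(path, factors = NULL, run_col = NULL,
                            response_col = NULL) {
  if (!file.exists(path)) stop("screen CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3) stop("screen CSV needs run, factor and response columns")
  if (is.null(run_col)) run_col <- names(df)[1]
  if (!run_col %in% names(df)) stop("run column '", run_col, "' not in CSV")
  if (is.null(response_col)) response_col <- names(df)[ncol(df)]
  if (!all(response_col %in% names(df))) {
    stop("response column(s) missing from CSV: ",
         paste(setdiff(response_col, names(df)), collapse = ", "))
  }
  fac_cols <- setdiff(names(df), c(run_col, response_col))
  if (!is.null(factors)) {
    missing <- setdiff(factors$name, fac_cols)
    if (length(missing)) {
      stop("CSV lacks factor column(s): ", paste(missing, collapse = ", "))
    }
    fac_cols <- factors$name    # canonical order
  }
  X <- as.matrix(df[fac_cols])
  if (!is.numeric(X)) stop("factor columns must be numeric")

  coded <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (all(v %in% c(-1, 1))) {
      coded[, j] <- v
    } else if (!is.null(factors)) {
      lo <- factors$low[j]; hi <- factors$high[j]
      is_lo <- abs(v - lo) <= 1e-9 * abs(lo)
      is_hi <- abs(v - hi) <= 1e-9 * abs(hi)
      if (!all(is_lo | is_hi)) {
        stop("column '", fac_cols[j], "' is not two-level: values ",
             paste(unique(signif(v[!(is_lo | is_hi)], 6)), collapse = ", "),
             " match neither {-1, 1} nor {", lo, ", ", hi, "}")
      }
      coded[, j] <- ifelse(is_hi, 1, -1)
    } else {
      stop("column '", fac_cols[j], "' is not coded (-1/1) and no factor ",
           "table was supplied to interpret natural units; values: ",
           paste(unique(signif(v[!v %in% c(-1, 1)], 6)), collapse = ", "))
    }
  }

  y <- as.matrix(df[response_col])
  if (!is.numeric(y)) stop("response column(s) must be numeric")
  if (ncol(y) > 1) {
    message("averaging ", ncol(y), " replicate response columns per run")
  }
  y <- rowMeans(y)
  if (any(!is.finite(y))) stop("responses must be finite")
  if (any(y < 0)) stop("growth rates must be non-negative")
  list(design = screen_design(coded, factors = factors, runs = df[[run_col]]),
       response = y)
}

#' @rdname read_screen_csv
#' @param design a [screen_design()].
#' @param response numeric response vector, one value per run.
#' @param digits decimal places written (default 6; round-trips exactly at
#'   that precision).
#' @return `write_screen_csv()`: the path, invisibly.
#' @export
write_screen_csv <- function(design, response, path, digits = 6,
                             response_col = "growth_rate") {
  stopifnot(inherits(design, "pb_design"))
  if (length(response) != nrow(design$coded)) {
    stop("response length ", length(response), " does not match ",
         nrow(design$coded), " runs")
  }
  df <- data.frame(trial = design$runs, design$coded,
                   check.names = FALSE)
  df[[response_col]] <- round(response, digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
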