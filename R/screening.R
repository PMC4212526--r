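#' Range analysis of a two-level screen
#'
#' For each factor, compares the mean response at the high level (`t1`)
#' with the mean at the low level (`t2`); the range `R = |t1 - t2|` ranks
#' the factors by influence. The reported `T1`/`T2` follow the convention
#' of the shipped case study's printed table: `T = 2 t`, i.e. twice the
#' level mean (equivalently, for a 12-run screen performed in triplicate,
#' the level sum divided by 3), not the raw level sum.
#'
#' @param design a [screen_design()].
#' @param response numeric response vector, one value per run.
#' @return A data frame of class `"range_table"` with one row per factor:
#'   `factor`, `T1`, `T2`, `t1`, `t2`, `R`, `rank` (1 = largest `R`; ties
#'   broken by factor order).
#' @examples
#' scr <- cho_screen()
#' range_analysis(scr$design, scr$response)
#' @export
range_analysis <- function(design, response) {
  stopifnot(inherits(design, "pb_design"))
  X <- design$coded
  y <- as.numeric(response)
  if (length(y) != nrow(X)) {
    stop("response length ", length(y), " does not match ", nrow(X), " runs")
  }
  if (any(!is.finite(y))) stop("responses must be finite")
  const <- vapply(seq_len(ncol(X)), function(j) length(unique(X[, j])) == 1L,
                  logical(1))
  if (any(const)) {
    stop("factor(s) set at a single level (contrast undefined): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  t1 <- vapply(seq_len(ncol(X)), function(j) mean(y[X[, j] == 1]), numeric(1))
  t2 <- vapply(seq_len(ncol(X)), function(j) mean(y[X[, j] == -1]), numeric(1))
  R <- abs(t1 - t2)
  out <- data.frame(factor = colnames(X), T1 = 2 * t1, T2 = 2 * t2,
                    t1 = t1, t2 = t2, R = R,
                    rank = rank(-R, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("range_table", "data.frame")
  out
}

#' Single-degree-of-freedom contrast ANOVA for an orthogonal screen
#'
#' Decomposes the total sum of squares of a balanced orthogonal two-level
#' design into one single-df contrast per factor plus a pooled residual.
#' For factor j with contrast `c_j = sum(y at +1) - sum(y at -1)`,
#' `SS_j = c_j^2 / n`; the error term pools what the m factor contrasts do
#' not explain, with `df_error = n - 1 - m`. Each factor is tested with
#' `F_j = MS_j / MS_error` against the F(1, df_error) distribution.
#'
#' @inheritParams range_analysis
#' @return A data frame of class `"pb_anova"`: one row per factor plus
#'   `Error` and `Total` rows, with columns `source`, `df`, `SS`, `MS`,
#'   `F`, `p`. When the response is constant every `SS` is 0 and `F`/`p`
#'   are `NaN` with a warning.
#' @examples
#' scr <- cho_screen()
#' pb_anova(scr$design, scr$response)
#' @export
pb_anova <- function(design, response) {
  stopifnot(inherits(design, "pb_design"))
  X <- design$coded
  y <- as.numeric(response)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) {
    stop("response length ", length(y), " does not match ", n, " runs")
  }
  if (any(!is.finite(y))) stop("responses must be finite")
  df_err <- n - 1L - m
  if (df_err < 1L) {
    stop("saturated design: no residual degrees of freedom left for an ",
         "error term (n - 1 - m = ", df_err, "); screen fewer factors or ",
         "use a larger design")
  }
  contrast <- as.numeric(crossprod(X, y))
  SS <- contrast^2 / n
  SS_tot <- sum(y^2) - sum(y)^2 / n
  # an (effectively) constant response has no variance to decompose; snap
  # the floating-point residue of the cancellation to exact zeros
  if (SS_tot <= 1e-12 * max(sum(y^2), 1)) {
    SS_tot <- 0
    SS[] <- 0
  }
  SS_err <- SS_tot - sum(SS)
  if (SS_err < 0 && SS_err > -1e-10 * max(SS_tot, 1)) SS_err <- 0
  MS_err <- SS_err / df_err
  if (MS_err == 0) {
    warning("zero residual mean square: F statistics are undefined (0/0)")
  }
  Fv <- SS / MS_err
  p <- stats::pf(Fv, 1, df_err, lower.tail = FALSE)
  out <- data.frame(
    source = c(colnames(X), "Error", "Total"),
    df = c(rep(1L, m), df_err, n - 1L),
    SS = c(SS, SS_err, SS_tot),
    MS = c(SS, MS_err, NA_real_),
    F = c(Fv, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pb_anova", "data.frame")
  out
}

#' Factors significant in a screening ANOVA
#'
#' @param anova a [pb_anova()] table.
#' @param alpha significance level (the screen's convention is 0.05).
#' @return Character vector of factor names with `p < alpha`, ordered by
#'   descending F statistic.
#' @examples
#' scr <- cho_screen()
#' significant_factors(pb_anova(scr$design, scr$response))        # X5, X4
#' significant_factors(pb_anova(scr$design, scr$response), 0.10)  # + X1
#' @export
significant_factors <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "pb_anova"))
  fac <- anova[!anova$source %in% c("Error", "Total"), ]
  hit <- fac[!is.na(fac$p) & fac$p < alpha, ]
  hit$source[order(-hit$F)]
}

#' @export
print.range_table <- function(x, digits = 4, ...) {
  cat("Range analysis (T = 2 x level mean; R = |t1 - t2|)\n")
  df <- x
  for (cl in c("T1", "T2", "t1", "t2", "R")) df[[cl]] <- round(df[[cl]], digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.pb_anova <- function(x, ...) {
  cat("Contrast ANOVA (single-df factor contrasts, pooled error)\n")
  df <- data.frame(source = x$source, df = x$df,
                   SS = round(x$SS, 4), MS = round(x$MS, 4),
                   F = round(x$F, 2), p = round(x$p, 4))
  df[is.na(df)] <- ""
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' Write screening reports as CSV
#'
#' Plain CSV mirrors of the range-analysis and ANOVA tables, at full
#' precision.
#'
#' @param x a `"range_table"` or `"pb_anova"` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
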