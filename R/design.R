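# Plackett-Burman first rows (cyclic generators); subsequent rows are
# cyclic shifts, the final row is all -1.
.pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1, 1,
           -1, -1, -1, -1)
)

#' Construct a two-level screening design
#'
#' Bundles a coded run matrix (entries -1/+1) with optional natural-unit
#' factor definitions. The constructor enforces the two defining invariants
#' of a Plackett-Burman array in exact integer arithmetic: every column is
#' balanced (equal counts of -1 and +1) and every pair of distinct columns
#' is orthogonal (zero dot product).
#'
#' @param coded numeric/integer matrix of -1/+1 entries, runs in rows.
#' @param factors optional [factor_table()] with one row per design column;
#'   column names of `coded` default to the factor names.
#' @param runs optional run identifiers (default `1:n`, matching the usual
#'   "Trial" numbering of printed designs).
#' @param validate check balance/orthogonality (default `TRUE`). Disable
#'   only for deliberately non-orthogonal layouts.
#' @return An object of class `"pb_design"`: a list with elements `coded`
#'   (integer matrix), `factors` (or `NULL`) and `runs`.
#' @seealso [pb_design()] to generate a standard array, [cho_screen()] for
#'   the packaged CHO screen.
#' @export
screen_design <- function(coded, factors = NULL, runs = NULL, validate = TRUE) {
  coded <- as.matrix(coded)
  if (!all(coded %in% c(-1, 1))) {
    bad <- unique(coded[!coded %in% c(-1, 1)])
    stop("coded entries must be -1 or +1; found: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  storage.mode(coded) <- "integer"
  n <- nrow(coded); m <- ncol(coded)
  if (is.null(runs)) runs <- seq_len(n)
  if (length(runs) != n) stop("length(runs) must equal nrow(coded)")
  if (!is.null(factors)) {
    if (!inherits(factors, "factor_table")) stop("factors must be a factor_table")
    if (nrow(factors) != m) {
      stop("factor table has ", nrow(factors), " rows but design has ",
           m, " columns")
    }
    colnames(coded) <- factors$name
  } else if (is.null(colnames(coded))) {
    colnames(coded) <- paste0("X", seq_len(m))
  }
  rownames(coded) <- as.character(runs)
  if (validate) {
    cs <- colSums(coded)
    if (any(cs != 0L)) {
      stop("unbalanced column(s): ",
           paste(colnames(coded)[cs != 0L], collapse = ", "))
    }
    xtx <- crossprod(coded)
    off <- xtx[upper.tri(xtx)]
    if (any(off != 0L)) stop("design columns are not mutually orthogonal")
  }
  structure(list(coded = coded, factors = factors, runs = runs),
            class = "pb_design")
}

#' Generate a standard Plackett-Burman design
#'
#' Builds the cyclic-generator Plackett-Burman array: the published first
#' row is shifted cyclically to give `n_runs - 1` rows and a final all-low
#' run is appended; the first `m` columns are returned. All generated
#' arrays are balanced and mutually orthogonal, so up to `n_runs - 1` main
#' effects can be screened in `n_runs` experiments (interactions are
#' aliased with main effects and are not estimable).
#'
#' @param n_runs number of runs; one of 8, 12, 16, 20, 24.
#' @param m number of factors, at most `n_runs - 1`.
#' @param factors optional [factor_table()] with `m` rows.
#' @return A [screen_design()] of dimension `n_runs` by `m`.
#' @examples
#' d <- pb_design(12, 7)
#' colSums(d$coded)        # all zero: balance
#' crossprod(d$coded)      # diagonal: orthogonality
#' @export
pb_design <- function(n_runs, m, factors = NULL) {
  key <- as.character(n_runs)
  if (!key %in% names(.pb_generators)) {
    stop("unsupported run count ", n_runs, "; supported sizes: ",
         paste(names(.pb_generators), collapse = ", "))
  }
  if (m < 1 || m > n_runs - 1) {
    stop("m must be between 1 and n_runs - 1 (= ", n_runs - 1L, "), got ", m)
  }
  g <- .pb_generators[[key]]
  k <- length(g)
  rows <- t(vapply(0:(k - 1L), function(s) g[((seq_len(k) - 1L + s) %% k) + 1L],
                   numeric(k)))
  full <- rbind(rows, rep(-1, k))
  screen_design(full[, seq_len(m), drop = FALSE], factors = factors)
}

#' Convert a design between coded and natural units
#'
#' `decode_levels()` maps coded levels to natural-unit concentrations via
#' the affine rule `u = midpoint + coded * half_range`, so -1 gives `low`,
#' +1 gives `high` and 0 gives the midpoint. `encode_levels()` is its
#' inverse for an arbitrary natural-unit matrix.
#'
#' @param design a [screen_design()] with a factor table, or a coded matrix
#'   (then `factors` must be supplied).
#' @param factors a [factor_table()]; taken from `design` if present.
#' @return `decode_levels()`: a numeric matrix of natural-unit settings.
#' @examples
#' d <- cho_screen()$design
#' decode_levels(d)[1, ]   # run 1 in mg/L / mmol/L
#' @export
decode_levels <- function(design, factors = NULL) {
  coded <- if (inherits(design, "pb_design")) design$coded else as.matrix(design)
  if (is.null(factors) && inherits(design, "pb_design")) factors <- design$factors
  if (is.null(factors)) stop("no factor table available to decode levels")
  if (ncol(coded) != nrow(factors)) {
    stop("design has ", ncol(coded), " columns but factor table has ",
         nrow(factors), " rows")
  }
  mid <- (factors$high + factors$low) / 2
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(coded, 2, half, "*"), 2, mid, "+")
  dimnames(out) <- dimnames(coded)
  out
}

#' @rdname decode_levels
#' @param natural numeric matrix of natural-unit settings.
#' @param snap snap values within relative tolerance `1e-9` of a level to
#'   exactly -1/+1 (default `TRUE`).
#' @return `encode_levels()`: a numeric matrix of coded settings.
#' @export
encode_levels <- function(natural, factors, snap = TRUE) {
  natural <- as.matrix(natural)
  if (ncol(natural) != nrow(factors)) {
    stop("natural matrix has ", ncol(natural), " columns but factor table has ",
         nrow(factors), " rows")
  }
  mid <- (factors$high + factors$low) / 2
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(natural, 2, mid, "-"), 2, half, "/")
  if (snap) {
    out[abs(out - 1) < 1e-9] <- 1
    out[abs(out + 1) < 1e-9] <- -1
  }
  dimnames(out) <- dimnames(natural)
  out
}

#' @export
print.pb_design <- function(x, ...) {
  cat("Plackett-Burman screen: ", nrow(x$coded), " runs x ",
      ncol(x$coded), " factors\n", sep = "")
  print(x$coded)
  if (!is.null(x$factors)) {
    cat("\n"); print(x$factors)
  }
  invisible(x)
}
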