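#' Define a set of two-level screening factors
#'
#' A factor table records, for each medium supplement (or any screened
#' variable), the natural-unit concentration assigned to the coded low
#' (\code{-1}) and high (\code{+1}) levels.
#'
#' @param name character vector of short factor identifiers (e.g. `"ZnSO4"`).
#' @param low,high numeric vectors of natural-unit levels; `low < high` and
#'   both must be strictly positive (they are concentrations).
#' @param units character vector of unit strings (e.g. `"mg/L"`).
#' @param label optional display names; defaults to `name`.
#' @return A data frame of class `"factor_table"` with columns
#'   `name`, `label`, `low`, `high`, `units`.
#' @examples
#' factor_table(name = c("ZnSO4", "BSA"), low = c(0.4, 80), high = c(1, 200),
#'              units = c("mg/L", "mg/L"))
#' @export
factor_table <- function(name, low, high, units, label = name) {
  stopifnot(is.character(name), length(name) >= 1L)
  n <- length(name)
  if (anyDuplicated(name)) stop("factor names must be unique")
  low <- as.numeric(low); high <- as.numeric(high)
  if (length(low) != n || length(high) != n || length(units) != n ||
      length(label) != n) {
    stop("name, low, high, units and label must have equal length")
  }
  if (any(!is.finite(low)) || any(!is.finite(high))) {
    stop("factor levels must be finite")
  }
  if (any(low <= 0) || any(high <= 0)) {
    stop("factor levels must be strictly positive concentrations")
  }
  if (any(low >= high)) {
    bad <- name[low >= high]
    stop("'low' must be below 'high' for factor(s): ", paste(bad, collapse = ", "))
  }
  if (any(!nzchar(units))) stop("units must be nonempty")
  out <- data.frame(name = name, label = as.character(label),
                    low = low, high = high, units = as.character(units),
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_table", "data.frame")
  out
}

#' The seven CHO serum-free-medium supplements of the shipped screen
#'
#' Levels for the 12-run screen of seven supplements to a serum-free
#' CHO-cell medium: ZnSO4, transferrin, putrescine, BSA, ferric citrate,
#' sodium pyruvate and ethanolamine. The coded low level is the leaner
#' medium; the high level the enriched one.
#'
#' @return A [factor_table()] with seven rows, named `X1` ... `X7`.
#' @examples
#' cho_factors()
#' @export
cho_factors <- function() {
  factor_table(
    name  = paste0("X", 1:7),
    label = c("ZnSO4", "transferrin", "putrescine", "BSA",
              "ferric citrate", "sodium pyruvate", "ethanolamine"),
    low   = c(0.4, 4, 0.4, 80, 0.3, 0.3, 2),
    high  = c(1, 10, 1, 200, 1, 1, 6),
    units = c("mg/L", "mg/L", "mg/L", "mg/L", "mmol/L", "mmol/L", "mg/L")
  )
}

#' Read factor definitions from a YAML or JSON config
#'
#' The config is a list of factor blocks, each with fields `name`, `low`,
#' `high`, `units` and optionally `label`, either at the top level or under
#' a `factors:` key:
#' \preformatted{
#' factors:
#'   - {name: X1, label: ZnSO4, low: 0.4, high: 1, units: mg/L}
#' }
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [factor_table()].
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  blocks <- if (is.list(cfg) && !is.null(cfg$factors)) cfg$factors else cfg
  if (!length(blocks)) stop("no factor definitions found in ", path)
  field <- function(b, f) if (is.null(b[[f]])) NA else b[[f]]
  nm  <- vapply(blocks, function(b) as.character(field(b, "name")), character(1))
  lbl <- vapply(blocks, function(b) as.character(field(b, "label")), character(1))
  lo  <- vapply(blocks, function(b) as.numeric(field(b, "low")), numeric(1))
  hi  <- vapply(blocks, function(b) as.numeric(field(b, "high")), numeric(1))
  un  <- vapply(blocks, function(b) as.character(field(b, "units")), character(1))
  if (anyNA(nm) || anyNA(lo) || anyNA(hi) || anyNA(un)) {
    stop("each factor block needs fields name, low, high, units")
  }
  lbl[is.na(lbl)] <- nm[is.na(lbl)]
  factor_table(name = nm, low = lo, high = hi, units = un, label = lbl)
}

#' @export
print.factor_table <- function(x, ...) {
  cat("Two-level factor set (", nrow(x), " factors)\n", sep = "")
  df <- data.frame(factor = x$name, label = x$label,
                   `low (-1)` = x$low, `high (+1)` = x$high,
                   units = x$units, check.names = FALSE)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
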