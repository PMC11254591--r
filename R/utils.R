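#' Truncate a monetary amount to whole euros
#'
#' Reported euro aggregates are truncated (not rounded) to whole euros. A small
#' tolerance is added towards zero-distance before truncation so that values
#' that are whole euros up to floating-point representation error (e.g.
#' `150.99999999997`) truncate to the intended integer.
#'
#' @param x numeric vector of euro amounts.
#' @param tol guard tolerance against representation error.
#' @return integer-valued numeric vector.
#' @export
trunc_eur <- function(x, tol = 1e-6) {
  trunc(x + sign(x) * tol)
}

#' Round a percentage to one decimal, half away from zero
#'
#' @param x numeric vector of percentages.
#' @return numeric vector rounded to one decimal with halves rounded up in
#'   magnitude (so 7.65 -> 7.7), unlike banker's rounding in [round()].
#' @export
round_pct1 <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5 + 1e-9) / 10
}

#' Present-value discount factors for annual model cycles
#'
#' Year 1 is undiscounted; year t is divided by (1+rate)^(t-1).
#'
#' @param rate annual discount rate (fraction, e.g. 0.03).
#' @param horizon number of model years.
#' @return numeric vector of length `horizon`.
#' @keywords internal
discount_factors <- function(rate, horizon) {
  (1 + rate)^-(seq_len(horizon) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a dotted path inside a nested list
#' @keywords internal
get_path <- function(x, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (is.null(x[[key]])) stop("unresolvable parameter path: '", path, "'", call. = FALSE)
    x <- x[[key]]
  }
  x
}

#' Set a value at a dotted path inside a nested list
#' @keywords internal
set_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(keys) == 1L) {
    if (is.null(x[[keys]])) stop("unresolvable parameter path: '", path, "'", call. = FALSE)
    x[[keys]] <- value
    return(x)
  }
  head <- keys[1L]
  if (is.null(x[[head]])) stop("unresolvable parameter path: '", path, "'", call. = FALSE)
  x[[head]] <- set_path(x[[head]], paste(keys[-1L], collapse = "."), value)
  x
}

stopifnot_fraction <- function(x, what) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    stop("validation error at ", what, ": value ", paste(x[bad], collapse = ", "),
         " outside [0,1]", call. = FALSE)
  }
  invisible(x)
}
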