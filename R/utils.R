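#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Round half up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for all reported prevalences (internal arithmetic stays at full
#' precision; rounding happens only at the reporting edge).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # the 1e-9 guard keeps decimal halves stored just below .5 (e.g. 34.05 * 10)
  # rounding up as intended
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("endgamesim_validation_error", "error")))
}

check_prob <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop_validation(what, " contains missing or non-finite values")
  }
  if (any(x < 0) || any(x > 1)) {
    stop_validation(what, " must lie in [0, 1]")
  }
  invisible(x)
}

# cheap fingerprint of an R object, used to stamp outputs for reproducibility
config_fingerprint <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
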