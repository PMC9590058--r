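# Internal helpers shared across modules.

# Error signalling ----------------------------------------------------------
# All user-facing errors carry a subclass so callers (and the CLI) can
# distinguish bad input from programming errors.

stop_invalid <- function(msg, ...) {
  rlang::abort(msg, class = c("peddose_invalid_input", "peddose_error"), ...)
}

stop_basis_mismatch <- function(msg, ...) {
  rlang::abort(msg, class = c("peddose_basis_mismatch", "peddose_error"), ...)
}

stop_missing_field <- function(msg, ...) {
  rlang::abort(msg, class = c("peddose_missing_field", "peddose_error"), ...)
}

stop_config <- function(msg, ...) {
  rlang::abort(msg, class = c("peddose_config_error", "peddose_error"), ...)
}

stop_unsupported <- function(msg, ...) {
  rlang::abort(msg, class = c("peddose_unsupported_scenario", "peddose_error"), ...)
}

# Validation ----------------------------------------------------------------

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)) ||
      any(x <= 0)) {
    bad <- if (is.numeric(x) && length(x) > 0L) {
      x[!is.finite(x) | is.na(x) | x <= 0][1L]
    } else {
      x
    }
    stop_invalid(sprintf(
      "`%s` must be a positive finite number; got %s.",
      what, paste(format(bad), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic commercial rounding (0.5 always moves away from zero),
#' used when formatting percents for reports; internal arithmetic is never
#' rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(0.5)   # 1
#' round_half_out(-0.5)  # -1
#' round_half_out(87.05, 1)
#' @export
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  # the sqrt(eps) nudge absorbs binary representation error in values
  # like 87.05 that sit just below the half-way point after scaling
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
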