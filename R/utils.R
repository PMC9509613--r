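# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and tests) can distinguish configuration errors from data-integrity
#' errors.
#'
#' @param msg message.
#' @param class condition class suffix, e.g. "config_error".
#' @noRd
stop_seqgp <- function(msg, class) {
  stop(structure(
    class = c(paste0("seqgp_", class), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_seqgp(sprintf("`%s` must be a single finite number", name),
               "config_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_seqgp(sprintf("`%s` = %g is outside its allowed range", name, x),
               "config_error")
  }
  invisible(x)
}

#' Derive a stage seed from a global seed
#'
#' Stage seeds are the global seed plus a documented fixed offset, folded
#' into the 32-bit integer range so they remain valid arguments to
#' [set.seed()].
#'
#' @param seed global integer seed.
#' @param offset fixed per-stage offset.
#' @return an integer seed.
#' @keywords internal
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483647)
}

#' Population variance (divisor n)
#' @noRd
popvar <- function(x) {
  mean((x - mean(x))^2)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
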