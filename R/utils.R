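# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed error
#'
#' All user-facing errors in the package carry a subclass of
#' `fawstrain_error` so callers (and the command-line wrapper) can react to
#' the error category rather than match on message text.
#'
#' @param msg message (sprintf-style with `...`).
#' @param class error subclass, e.g. "fawstrain_format_error".
#' @param ... sprintf arguments.
#' @noRd
faw_abort <- function(msg, class = "fawstrain_error", ...) {
  if (length(list(...)) > 0L) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "fawstrain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

faw_warn <- function(msg, ...) {
  if (length(list(...)) > 0L) msg <- sprintf(msg, ...)
  warning(msg, call. = FALSE)
}

# Collapse a character vector of flags into the single ";"-separated token
# used in output tables ("" when no flags).
collapse_flags <- function(flags) {
  if (length(flags) == 0L) "" else paste(unique(flags), collapse = ";")
}

# Draw from a Normal truncated above at `upper` (inverse-CDF method, exact
# and vectorised; used by the Cq simulator to keep late signals inside the
# cycling program).
rnorm_upper <- function(n, mean, sd, upper) {
  if (sd <= 0) return(rep(min(mean, upper), n))
  u <- stats::runif(n) * stats::pnorm((upper - mean) / sd)
  # guard against u == 0 underflow for extreme truncation
  u <- pmax(u, .Machine$double.xmin)
  mean + sd * stats::qnorm(u)
}

# Deterministic child seed derivation: keeps every derived seed a valid
# 32-bit integer whatever small integer the user supplies.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
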