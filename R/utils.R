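#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus an arbitrary sequence of integer
#' indices to a new seed in `[0, 2^31 - 2]`.  Used for the seed cascade
#' (master seed -> per-repeat seed -> per-fold model seed) so that any repeat
#' of a resampling scheme is reproducible in isolation.
#'
#' @param seed integer master seed.
#' @param ... integer indices (repeat number, fold number, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  s <- 0
  # multiplicative hash in double precision; 69069 * 2^31 < 2^53 so exact
  for (v in idx) s <- (s * 69069 + as.double(v) + 1) %% 2147483647
  as.integer(s)
}

# internal: stop() with a classed condition so callers can distinguish
# argument errors from contract/validation errors
.voc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "vocclass_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.arg_error <- function(msg) .voc_stop(msg, "vocclass_argument_error")
.contract_error <- function(msg) .voc_stop(msg, "vocclass_contract_error")
.format_error <- function(msg) .voc_stop(msg, "vocclass_format_error")
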