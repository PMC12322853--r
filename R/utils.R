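# Internal condition helpers: every user-facing error carries a condition
# class so callers (and tests) can distinguish invalid input from
# inconsistency, degeneracy, etc.

mv_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "macbethvaf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_invalid <- function(message, ...) mv_stop(message, "mv_invalid_input", ...)
stop_degenerate <- function(message, ...) mv_stop(message, "mv_degenerate", ...)
stop_inconsistent <- function(message, ...) mv_stop(message, "mv_inconsistent", ...)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
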