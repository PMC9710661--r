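# internal helpers: classed conditions so callers (and the CLI) can map
# failure modes to exit codes without string-matching messages

md_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "markerdens_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    md_stop(sprintf("`%s` must be a single number in [0, 1]", name),
            "markerdens_parameter_error")
  invisible(x)
}

# x * log(x) with the 0 * log(0) = 0 convention used throughout the
# Jensen-Shannon computations
xlogx <- function(x) {
  r <- x * log(x)
  r[x == 0] <- 0
  r
}
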