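# Classed error conditions so callers and tests can discriminate failure
# modes without matching message text.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rotometry_error"),
                      call = call))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          "rotometry_invalid_input")
  }
  invisible(x)
}
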