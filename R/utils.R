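`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "qa4dct_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "qa4dct_error")))
}

#' @noRd
check_number <- function(x, name, min = -Inf, max = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stopf("'%s' must be numeric of length %d", name, len, class = "qa4dct_validation_error")
  }
  if (any(x < min) || any(x > max)) {
    stopf("'%s' out of range [%g, %g]: %s", name, min, max,
          paste(signif(x, 6), collapse = ", "),
          class = "qa4dct_validation_error")
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# HU dynamic range of a 12-bit CT scale
HU_MIN <- -1024
HU_MAX <- 3071
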