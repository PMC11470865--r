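# classed conditions so callers can distinguish validation, domain and
# schema failures programmatically

frt_stop <- function(class, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "frtnorms_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

frt_validation_error <- function(msg, ...) {
  frt_stop("frt_validation_error", msg, ...)
}

frt_domain_error <- function(msg, ...) {
  frt_stop("frt_domain_error", msg, ...)
}

frt_schema_error <- function(msg, ...) {
  frt_stop("frt_schema_error", msg, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    frt_domain_error(sprintf(
      "'%s' must be a single finite number in [%s, %s]", name,
      format(lo), format(hi)
    ))
  }
  invisible(x)
}

match_subscale <- function(subscale) {
  if (!is.character(subscale) || length(subscale) != 1L ||
      !subscale %in% frt_subscales) {
    frt_domain_error(sprintf(
      "unknown subscale '%s'; must be one of: %s",
      paste(subscale, collapse = ","), paste(frt_subscales, collapse = ", ")
    ))
  }
  subscale
}

# stderr logging used by the pipeline; data never goes to stdout/stderr
frt_log <- function(fmt, ...) {
  message(sprintf(paste0("[frtnorms] ", fmt), ...))
}
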