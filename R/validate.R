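# Internal validation helpers. Errors are raised without the call so that
# user-facing messages name the offending field, not internal frames.

abort <- function(...) {
  stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("'%s' must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "'%s' = %s is outside the allowed range %s%s, %s%s", name,
      format(x), if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name, lower = 0, upper = 1)
}

# Count-matrix inputs are accepted either as a count_matrix object or as a
# plain named integer matrix; this funnels both into the matrix.
as_counts <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "count_matrix")) {
    return(x$counts)
  }
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort(sprintf("'%s' must have feature rownames and sample colnames", arg))
    }
    return(x)
  }
  abort(sprintf("'%s' must be a count_matrix or a named numeric matrix", arg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
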