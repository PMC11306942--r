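#' @importFrom rlang abort warn %||% .data
#' @importFrom stats var sd qnorm qf pt qt pf setNames aggregate complete.cases
#' @importFrom utils head tail
NULL

stop_input <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "stepconcord_input_error")
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_nonneg_int <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0) else is.na(x) | x < 0
  if (any(bad)) {
    stop_input(sprintf(
      "column '%s' must contain non-negative %svalues; first bad row: %d",
      name, if (allow_na) "or missing " else "", which(bad)[1L]
    ))
  }
  invisible(x)
}

# scalar flag check
assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("'%s' must be TRUE or FALSE", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
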