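#' @importFrom rlang abort
NULL

stop_bad <- function(msg, class = "hybridclamp_error") {
  rlang::abort(msg, class = class)
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop_bad(sprintf("`%s` must be finite (got %s)", what,
                     paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")),
             class = "hybridclamp_nonfinite")
  }
  invisible(x)
}

assert_scalar_pos <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_bad(sprintf("`%s` must be a positive finite scalar", what))
  }
  invisible(x)
}

# Coerce a trace argument to a (time, v) tibble.  Accepts a data frame with
# time/v(-like) columns or a bare numeric vector plus sampling rate.
as_trace <- function(trace, fs = NULL) {
  if (is.data.frame(trace)) {
    nm <- names(trace)
    tcol <- intersect(c("time", "t"), nm)[1]
    vcol <- intersect(c("v", "v_mv", "voltage", "v_live"), nm)[1]
    if (is.na(tcol) || is.na(vcol)) {
      stop_bad("trace data frame needs a time column ('time') and a voltage column ('v')")
    }
    tibble::tibble(time = as.numeric(trace[[tcol]]), v = as.numeric(trace[[vcol]]))
  } else if (is.numeric(trace)) {
    if (is.null(fs)) stop_bad("`fs` is required when `trace` is a bare numeric vector")
    tibble::tibble(time = seq_along(trace) / fs - 1 / fs, v = as.numeric(trace))
  } else {
    stop_bad("`trace` must be a data frame or numeric vector")
  }
}

trace_fs <- function(trace_df, fs = NULL) {
  if (!is.null(fs)) return(fs)
  dt <- diff(trace_df$time[seq_len(min(11L, nrow(trace_df)))])
  1 / stats::median(dt)
}
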