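#' Tabulate an expensive nonlinearity
#'
#' Conductance-based models spend most of their per-step cost in exponential
#' rate and steady-state functions.  `tabulate_fn()` samples such a function
#' on a uniform grid once, so that later evaluations reduce to a linear
#' interpolation; queries outside the tabulated domain clamp to the boundary
#' values.
#'
#' @param fn Function of one numeric argument, finite on `[lo, hi]`.
#' @param lo,hi Domain bounds (same units as the argument of `fn`).
#' @param n_nodes Number of grid nodes (>= 2).
#' @return An object of class `lookup_table`.
#' @examples
#' tab <- tabulate_fn(exp, -2, 0, 101)
#' table_eval(tab, -1) # ~ exp(-1)
#' @export
tabulate_fn <- function(fn, lo, hi, n_nodes = 10001L) {
  if (!is.function(fn)) stop_bad("`fn` must be a function")
  if (!(lo < hi)) stop_bad("`lo` must be < `hi`")
  if (n_nodes < 2L) stop_bad("`n_nodes` must be >= 2")
  x <- seq(lo, hi, length.out = n_nodes)
  y <- vapply(x, fn, numeric(1))
  bad <- which(!is.finite(y))
  if (length(bad)) {
    stop_bad(sprintf("`fn` is non-finite at node x = %g", x[bad[1]]),
             class = "hybridclamp_nonfinite")
  }
  structure(list(lo = lo, hi = hi, n = n_nodes, x = x, y = y,
                 step = (hi - lo) / (n_nodes - 1)),
            class = "lookup_table")
}

#' @rdname tabulate_fn
#' @param table A `lookup_table`.
#' @param v Query points; values outside the domain clamp to the boundary.
#' @export
table_eval <- function(table, v) {
  v <- pmin(pmax(v, table$lo), table$hi)
  i <- pmin(floor((v - table$lo) / table$step), table$n - 2)
  frac <- (v - (table$lo + i * table$step)) / table$step
  table$y[i + 1] * (1 - frac) + table$y[i + 2] * frac
}

# Scalar-optimised closure over a lookup table (hot-loop form).
table_fun <- function(table) {
  lo <- table$lo; hi <- table$hi; step <- table$step; y <- table$y
  nm2 <- table$n - 2
  function(v) {
    if (v < lo) v <- lo else if (v > hi) v <- hi
    i <- floor((v - lo) / step)
    if (i > nm2) i <- nm2
    frac <- (v - (lo + i * step)) / step
    y[i + 1] * (1 - frac) + y[i + 2] * frac
  }
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("<lookup_table> %d nodes on [%g, %g]\n", x$n, x$lo, x$hi))
  invisible(x)
}
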