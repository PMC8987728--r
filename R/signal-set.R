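#' Validate a collection of two-dimensional signals
#'
#' A signal set is a long-format data frame with one row per sampled point
#' and columns `signal` (label), `x`, and `y`. Each signal is an ordered
#' polyline; the row order within a signal is the sampling order. The
#' corridor method needs at least two signals, each with at least two
#' points, all values finite, and no zero-length segments (consecutive
#' duplicate points), so validation enforces exactly those rules:
#'
#' * rows with non-finite `x` or `y` are dropped with a warning,
#' * exact consecutive duplicate points are dropped with a warning (they
#'   contribute zero arc length and would break resampling),
#' * a signal left with fewer than 2 points is an error,
#' * fewer than 2 signals is an error (statistics over one signal are
#'   degenerate).
#'
#' @param data A data frame with columns `signal`, `x`, `y` (or columns
#'   identified by the `signal`, `x`, `y` arguments).
#' @param signal,x,y Column names (as strings) holding the signal label and
#'   the two coordinates. Defaults `"signal"`, `"x"`, `"y"`.
#'
#' @return A validated tibble with columns `signal` (character), `x`, `y`
#'   and class `"signal_set"`. Units are whatever the input used; the
#'   package never interprets them.
#'
#' @examples
#' df <- data.frame(
#'   signal = rep(c("a", "b"), each = 3),
#'   x = c(0, 1, 2, 0, 1.5, 3),
#'   y = c(0, 1, 1.5, 0, 0.8, 1.2)
#' )
#' as_signal_set(df)
#' @export
as_signal_set <- function(data, signal = "signal", x = "x", y = "y") {
  if (inherits(data, "signal_set")) {
    return(data)
  }
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns signal, x, y.")
  }
  missing_cols <- setdiff(c(signal, x, y), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble(
    signal = as.character(data[[signal]]),
    x = as.numeric(data[[x]]),
    y = as.numeric(data[[y]])
  )

  bad <- !is.finite(out$x) | !is.finite(out$y)
  if (any(bad)) {
    warn(paste0("Dropped ", sum(bad), " row(s) with non-finite coordinates."))
    out <- out[!bad, ]
  }

  # consecutive duplicate points carry zero segment length
  out <- out %>%
    group_by(.data$signal) %>%
    mutate(
      .dup = dplyr::row_number() > 1 &
        .data$x == lag(.data$x) & .data$y == lag(.data$y)
    ) %>%
    ungroup()
  if (any(out$.dup)) {
    warn(paste0(
      "Dropped ", sum(out$.dup),
      " consecutive duplicate point(s) (zero segment length)."
    ))
  }
  out <- out[!out$.dup, c("signal", "x", "y")]

  counts <- table(out$signal)
  if (any(counts < 2)) {
    abort(paste0(
      "Signal(s) with fewer than 2 points after cleaning: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  if (length(counts) < 2) {
    abort("Need at least 2 signals to compute an average and corridors.")
  }
  class(out) <- c("signal_set", class(out))
  out
}

#' Number of signals in a signal set
#' @param signals A signal set (see [as_signal_set()]).
#' @return Integer count of distinct signals.
#' @export
n_signals <- function(signals) {
  length(unique(signals$signal))
}
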