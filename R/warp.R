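#' Monotone warping function of normalized arc length
#'
#' A warping function remaps normalized arc length onto itself to align
#' features across signals: it is a monotone cubic Hermite (Fritsch-Carlson)
#' interpolating spline through `m` interior control points, anchored at
#' `(0, 0)` and `(1, 1)`. Monotonicity of the spline guarantees the warped
#' arc length never runs backwards, so warping re-times a signal without
#' changing its shape.
#'
#' @param s_interior,h_interior Interior control point coordinates, both
#'   strictly increasing and strictly inside `(0, 1)`; may be empty, in
#'   which case the warp is the identity.
#' @return An object of class `warp_function` with fields `s` and `h`
#'   holding the full (anchored) control polygons.
#' @seealso [eval_warp()]
#' @export
warp_function <- function(s_interior = numeric(), h_interior = numeric()) {
  if (length(s_interior) != length(h_interior)) {
    abort("`s_interior` and `h_interior` must have the same length.")
  }
  for (v in list(s_interior, h_interior)) {
    if (length(v) > 0 &&
      (any(v <= 0) || any(v >= 1) || any(diff(v) <= 0))) {
      abort(
        "Interior control points must be strictly increasing within (0, 1)."
      )
    }
  }
  structure(
    list(s = c(0, s_interior, 1), h = c(0, h_interior, 1)),
    class = "warp_function"
  )
}

#' Identity warp (no registration)
#' @return A `warp_function` with no interior control points.
#' @export
identity_warp <- function() warp_function()

#' Evaluate a warping function
#'
#' Evaluates the monotone cubic Hermite spline defined by the warp's
#' control points. With no interior control points the warp is exactly the
#' identity. Output is clamped to `[0, 1]` to guard against terminal
#' floating-point overshoot.
#'
#' @param warp A `warp_function`.
#' @param s Numeric vector of normalized arc lengths in `[0, 1]`.
#' @return Warped arc lengths `h(s)`, same length as `s`.
#' @examples
#' w <- warp_function(0.5, 0.25)
#' eval_warp(w, c(0, 0.5, 1)) # 0, 0.25, 1
#' @export
eval_warp <- function(warp, s) {
  stopifnot(inherits(warp, "warp_function"))
  if (length(warp$s) == 2) {
    return(s)
  }
  f <- splinefun(warp$s, warp$h, method = "monoH.FC")
  pmin(1, pmax(0, f(s)))
}

#' @export
print.warp_function <- function(x, ...) {
  m <- length(x$s) - 2
  if (m == 0) {
    cat("Identity warp (no interior control points)\n")
  } else {
    cat("Monotone warp with", m, "interior control point(s):\n")
    print(tibble(s = x$s, h = x$h))
  }
  invisible(x)
}

# Maximum absolute deviation of a warp from the identity on a dense grid.
warp_deviation <- function(warp, n_grid = 1001) {
  s <- seq(0, 1, length.out = n_grid)
  max(abs(eval_warp(warp, s) - s))
}
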