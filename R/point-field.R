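#' Physical extents of the observation channel
#'
#' Describes the physical (pixel or micrometre) extent of the rectangular
#' channel along each axis, used to map raw tracked positions onto the unit
#' square.  `x` is the cross axis (across the three fluid bands, the axis on
#' which a chemical landscape can exist), `y` the long axis (along the
#' channel, the control direction).
#'
#' @param x,y Numeric length-2 vectors `c(low, high)` with `high > low`.
#' @return An object of class `region_bounds`.
#' @examples
#' region_bounds(x = c(0, 1200), y = c(0, 4000))
#' @export
region_bounds <- function(x = c(0, 1), y = c(0, 1)) {
  for (axis in list(x = x, y = y)) {
    if (!is.numeric(axis) || length(axis) != 2 || anyNA(axis)) {
      stop("each axis of `region_bounds` must be a numeric c(low, high)",
           call. = FALSE)
    }
  }
  if (diff(x) <= 0 || diff(y) <= 0) {
    stop("degenerate region bounds: `high` must exceed `low` on every axis",
         call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "region_bounds")
}

#' @export
print.region_bounds <- function(x, ...) {
  cat(sprintf("<region_bounds> cross (x): [%g, %g]  long (y): [%g, %g]\n",
              x$x[1], x$x[2], x$y[1], x$y[2]))
  invisible(x)
}

#' Map raw tracked positions onto the unit square
#'
#' Applies the affine map taking the configured channel bounds onto
#' \eqn{[0,1]} on each axis.  The bounds are a fixed property of the device,
#' not of the frame: rescaling each frame by its own min/max would distort the
#' time evolution of the dispersion index.
#'
#' @param positions A data frame with numeric columns `x` and `y` (raw
#'   coordinates).  Rows with both coordinates `NA` (empty-frame markers) are
#'   passed through untouched.
#' @param bounds A [region_bounds()] object.
#' @return A tibble with the same rows and columns, `x` and `y` rescaled to
#'   `[0, 1]`.
#' @details A coordinate outside its axis bounds is an error (tolerance zero):
#'   tracked positions must lie inside the channel, so an excursion indicates
#'   mismatched bounds or corrupt input, not data to be clamped.
#' @examples
#' pts <- tibble::tibble(x = c(0, 10, 5), y = c(0, 5, 2.5))
#' normalize_positions(pts, region_bounds(x = c(0, 10), y = c(0, 5)))
#' @export
normalize_positions <- function(positions, bounds) {
  stopifnot(is.data.frame(positions))
  if (!inherits(bounds, "region_bounds")) {
    stop("`bounds` must be a region_bounds object", call. = FALSE)
  }
  if (!all(c("x", "y") %in% names(positions))) {
    stop("`positions` must have columns `x` and `y`", call. = FALSE)
  }
  out <- tibble::as_tibble(positions)
  marker <- is.na(out$x) & is.na(out$y)
  for (axis in c("x", "y")) {
    lo <- bounds[[axis]][1]
    hi <- bounds[[axis]][2]
    v <- out[[axis]]
    bad <- which(!marker & !is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0) {
      stop(sprintf(
        "position %d (%s = %g) lies outside the %s bounds [%g, %g]",
        bad[1], axis, v[bad[1]], axis, lo, hi), call. = FALSE)
    }
    if (anyNA(v[!marker])) {
      stop(sprintf("missing %s coordinate in a non-empty frame row", axis),
           call. = FALSE)
    }
    out[[axis]] <- (v - lo) / (hi - lo)
  }
  out
}

#' Extract a coordinate marginal as a 1-D point field
#'
#' Projects a set of 2-D positions onto one axis, yielding the 1-D point
#' process that the dispersion analysis consumes.  `"cross"` is the axis
#' across the three fluid bands (where chemotaxis acts, stored in column
#' `x`); `"long"` is the axis along the channel (the control direction,
#' column `y`).
#'
#' @param positions A data frame with numeric columns `x` and `y` in
#'   `[0, 1]`.  Empty-frame marker rows (`x` and `y` both `NA`) are dropped.
#' @param axis `"cross"` or `"long"`.
#' @return A numeric vector of positions in `[0, 1]`, in row order.
#' @examples
#' pts <- tibble::tibble(x = c(0.2, 0.4), y = c(0.9, 0.1))
#' marginal_positions(pts, "cross")
#' marginal_positions(pts, "long")
#' @export
marginal_positions <- function(positions, axis = c("cross", "long")) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(positions))
  if (!all(c("x", "y") %in% names(positions))) {
    stop("`positions` must have columns `x` and `y` (a 2-D point field)",
         call. = FALSE)
  }
  col <- if (axis == "cross") "x" else "y"
  v <- positions[[col]]
  v[!(is.na(positions$x) & is.na(positions$y))]
}

check_unit_positions <- function(x, what = "positions") {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", what), call. = FALSE)
  if (anyNA(x)) stop(sprintf("`%s` contains NA", what), call. = FALSE)
  if (length(x) > 0 && (min(x) < 0 || max(x) > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]; got value %g", what,
                 x[which(x < 0 | x > 1)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Quadrat counts over equal-width subintervals
#'
#' Divides `[0, 1]` into `k` subintervals of equal length and counts the
#' points in each.  Cell `i` (1-based) is the half-open interval
#' \eqn{[(i-1)/k, i/k)}; the last cell is closed at 1 so boundary points are
#' never lost.  The half-open convention is a choice (points falling exactly
#' on an interior cell edge are assigned to the right-hand cell); it avoids
#' double counting.
#'
#' @param x Numeric vector of 1-D positions in `[0, 1]`.
#' @param k Integer number of subintervals, at least 2.
#' @return An integer vector of length `k` summing to `length(x)`.
#' @examples
#' quadrat_counts(c(0.1, 0.5, 0.9), k = 2)
#' @export
quadrat_counts <- function(x, k) {
  if (length(k) != 1 || !is.finite(k) || k != round(k) || k < 2) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  check_unit_positions(x)
  k <- as.integer(k)
  if (length(x) == 0) return(integer(k))
  idx <- pmin(floor(x * k), k - 1L) + 1L
  tabulate(idx, nbins = k)
}

#' Count points in a subinterval
#'
#' Number of points of a 1-D field in `[a, b)`; the interval is closed at `b`
#' only when `b = 1`, matching the quadrat-cell convention.
#'
#' @param x Numeric vector of 1-D positions in `[0, 1]`.
#' @param interval Numeric `c(a, b)` with `0 <= a < b <= 1`.
#' @return An integer count.
#' @examples
#' count_in_interval(c(0.1, 0.5, 0.9), c(1 / 3, 2 / 3))
#' @export
count_in_interval <- function(x, interval) {
  if (length(interval) != 2 || anyNA(interval)) {
    stop("`interval` must be c(a, b)", call. = FALSE)
  }
  a <- interval[1]; b <- interval[2]
  if (a >= b) stop("`interval` must satisfy a < b", call. = FALSE)
  if (a < 0 || b > 1) stop("`interval` must lie within [0, 1]", call. = FALSE)
  check_unit_positions(x)
  if (length(x) == 0) return(0L)
  sum(x >= a & (x < b | (b == 1 & x <= 1)))
}
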