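#' Intensity estimate of a uniform Poisson process on the unit interval
#'
#' With the domain length normalised to 1, the maximum-likelihood estimate of
#' the intensity of a homogeneous Poisson process is simply the total number
#' of observed points.
#'
#' @param x Numeric vector of 1-D positions in `[0, 1]`.
#' @return The number of points (a non-negative integer).
#' @export
estimate_intensity <- function(x) {
  check_unit_positions(x)
  length(x)
}

#' Poisson probability of a count in a test set
#'
#' Probability of finding exactly `n` points of a homogeneous Poisson process
#' with the given intensity in a set of the given Lebesgue measure:
#' \eqn{e^{-\lambda|B|} (\lambda|B|)^n / n!}.  Evaluated in log space, so it
#' is stable for large \eqn{\lambda|B|} and `n`.
#'
#' @param intensity Non-negative intensity \eqn{\lambda}.
#' @param length Non-negative measure \eqn{|B|} of the test set.
#' @param n Non-negative integer count (vectorised).
#' @return Probabilities, one per element of `n`.
#' @examples
#' poisson_count_pmf(2, 1, 2) # 2 * exp(-2)
#' @export
poisson_count_pmf <- function(intensity, length, n) {
  if (!is.numeric(intensity) || intensity < 0) {
    stop("`intensity` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(length) || length < 0) {
    stop("`length` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != round(n))) {
    stop("`n` must be non-negative integers", call. = FALSE)
  }
  exp(stats::dpois(n, lambda = intensity * length, log = TRUE))
}

#' Dispersion index of quadrat counts
#'
#' The index of dispersion \eqn{I = (k - 1) S^2 / \bar N}, where \eqn{\bar N}
#' is the sample mean of the `k` quadrat counts and \eqn{S^2} their unbiased
#' sample variance (divisor `k - 1`).  Under the homogeneous-Poisson null the
#' counts are i.i.d. Poisson and `I` is approximately chi-squared with
#' `k - 1` degrees of freedom, which is what makes the two-sided quantile
#' test of [dispersion_bounds()] possible.
#'
#' @param counts Integer vector of quadrat counts, length `k >= 2`, with a
#'   positive total (an all-zero count vector leaves the intensity estimate
#'   at zero and the statistic undefined).
#' @return The dispersion index, a non-negative number.
#' @examples
#' dispersion_index(c(0, 1, 2, 3, 4)) # 5
#' dispersion_index(c(3, 3, 3, 3)) # 0
#' @export
dispersion_index <- function(counts) {
  if (!is.numeric(counts) || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  k <- length(counts)
  if (k < 2) stop("need at least k = 2 quadrat counts", call. = FALSE)
  if (sum(counts) == 0) {
    stop("all quadrat counts are zero: the intensity estimate is zero and the dispersion index is undefined",
         call. = FALSE)
  }
  (k - 1) * stats::var(counts) / mean(counts)
}

#' Two-sided chi-squared rejection bounds for the dispersion index
#'
#' The homogeneous-Poisson hypothesis is rejected when the dispersion index
#' falls strictly outside the central \eqn{1 - \alpha} region of the
#' chi-squared distribution with `k - 1` degrees of freedom: below the
#' \eqn{\alpha/2} quantile (counts too even, "regular") or above the
#' \eqn{1 - \alpha/2} quantile (counts too variable, "clustered").  The
#' smaller `alpha`, the wider the gap between the bounds.
#'
#' @param alpha Type-I error probability, in `(0, 1)`.
#' @param k Number of quadrat cells, integer `>= 2`.
#' @return Named numeric vector `c(lower = ..., upper = ...)`.
#' @examples
#' dispersion_bounds(0.05, k = 11)
#' @export
dispersion_bounds <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly within (0, 1)", call. = FALSE)
  }
  if (length(k) != 1 || !is.finite(k) || k != round(k) || k < 2) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  df <- k - 1
  c(lower = stats::qchisq(alpha / 2, df),
    upper = stats::qchisq(1 - alpha / 2, df))
}

#' Classify a dispersion index against its rejection bounds
#'
#' Rejection uses strict inequalities: a statistic exactly on a bound is
#' `"consistent"` with the homogeneous-Poisson null.
#'
#' @param statistic Dispersion index values (vectorised).
#' @param bounds Numeric `c(lower, upper)` with `lower < upper`, as returned
#'   by [dispersion_bounds()].
#' @return Character vector of verdicts: `"clustered"` (above the upper
#'   bound), `"regular"` (below the lower bound), or `"consistent"`.
#' @export
classify_dispersion <- function(statistic, bounds) {
  if (length(bounds) != 2 || anyNA(bounds) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  out <- rep("consistent", length(statistic))
  out[statistic > bounds[2]] <- "clustered"
  out[statistic < bounds[1]] <- "regular"
  out[is.na(statistic)] <- NA_character_
  out
}

#' Dispersion-index test at a single partition scale
#'
#' Convenience wrapper composing [quadrat_counts()], [dispersion_index()],
#' [dispersion_bounds()] and [classify_dispersion()] for one `k`.
#'
#' @param x Numeric vector of 1-D positions in `[0, 1]`, non-empty.
#' @param k Number of quadrat cells, integer `>= 2`.
#' @param alpha Type-I error probability (default 0.05).
#' @return A one-row tibble with columns `k`, `n`, `statistic`, `lower`,
#'   `upper`, `alpha`, `verdict`.
#' @examples
#' set.seed(1)
#' dispersion_test(runif(200), k = 10)
#' @export
dispersion_test <- function(x, k, alpha = 0.05) {
  if (length(x) == 0) stop("point field is empty", call. = FALSE)
  counts <- quadrat_counts(x, k)
  stat <- dispersion_index(counts)
  b <- dispersion_bounds(alpha, k)
  tibble::tibble(
    k = as.integer(k), n = length(x), statistic = stat,
    lower = unname(b["lower"]), upper = unname(b["upper"]),
    alpha = alpha, verdict = classify_dispersion(stat, b))
}

#' Multiscale dispersion-index sweep
#'
#' Runs the dispersion test over a range of partition scales.  A single `k`
#' fixes the contrast the test can see; sweeping `k` raises confidence in the
#' verdict.  The default `5:25` keeps the expected count per cell at or above
#' 8 for fields of roughly 200 points, where the chi-squared approximation to
#' the null is reliable.  No multiple-testing correction is applied across
#' scales: each row reports its own per-test `alpha`, mirroring per-scale
#' inspection of the sweep.
#'
#' @param x Numeric vector of 1-D positions in `[0, 1]`, non-empty.
#' @param k_range Strictly increasing integers `>= 2`.
#' @param alpha Type-I error probability shared by all scales.
#' @return A tibble of class `multiscale_dispersion`, one row per `k`, with
#'   the columns of [dispersion_test()].
#' @examples
#' set.seed(1)
#' multiscale_dispersion(runif(200), k_range = 5:10)
#' @export
multiscale_dispersion <- function(x, k_range = 5:25, alpha = 0.05) {
  if (length(x) == 0) stop("point field is empty", call. = FALSE)
  if (length(k_range) == 0) stop("`k_range` is empty", call. = FALSE)
  if (any(k_range < 2) || any(k_range != round(k_range))) {
    stop("every k in `k_range` must be an integer >= 2", call. = FALSE)
  }
  if (is.unsorted(k_range, strictly = TRUE)) {
    stop("`k_range` must be strictly increasing", call. = FALSE)
  }
  out <- purrr::map(k_range, function(k) dispersion_test(x, k, alpha))
  out <- dplyr::bind_rows(out)
  structure(out, class = c("multiscale_dispersion", class(out)),
            n = length(x), alpha = alpha)
}

#' Chemotactic index of a band-loaded channel
#'
#' Area-normalised density ratio between the chemically loaded central band
#' and the two unloaded side sections:
#' \eqn{(N_{in}/|band|) / (N_{out}/(1-|band|))}.  Normalising by the section
#' widths makes the index exactly 1 for a perfectly uniform field regardless
#' of the band geometry; values above 1 indicate accumulation in the band
#' (attraction), below 1 depletion (repulsion).
#'
#' @param x Numeric vector of cross-axis positions in `[0, 1]`, non-empty.
#' @param band Numeric `c(a, b)` giving the loaded band; default the central
#'   third.
#' @return A single number; `Inf` when every point lies inside the band.
#' @examples
#' chemotactic_index(c(runif(100, 1 / 3, 2 / 3), runif(100)), c(1 / 3, 2 / 3))
#' @export
chemotactic_index <- function(x, band = c(1 / 3, 2 / 3)) {
  if (length(x) == 0) stop("point field is empty", call. = FALSE)
  n_in <- count_in_interval(x, band)
  n_out <- length(x) - n_in
  w <- band[2] - band[1]
  if (n_out == 0) return(Inf)
  (n_in / w) / (n_out / (1 - w))
}
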