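#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a multiscale dispersion sweep
#'
#' @param x A `multiscale_dispersion` object.
#' @param ... Unused.
#' @return A plain tibble, one row per partition scale `k`.
#' @method tidy multiscale_dispersion
#' @export
tidy.multiscale_dispersion <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "n", "statistic", "lower", "upper",
                                 "alpha", "verdict")])
}

#' One-row summary of a multiscale dispersion sweep
#'
#' @param x A `multiscale_dispersion` object.
#' @param ... Unused.
#' @return A one-row tibble: points analysed, per-test `alpha`, number of
#'   scales, counts of each verdict, and the fraction of scales rejecting
#'   the homogeneous-Poisson null.
#' @method glance multiscale_dispersion
#' @export
glance.multiscale_dispersion <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), alpha = attr(x, "alpha"), n_scales = nrow(x),
    n_clustered = sum(x$verdict == "clustered"),
    n_regular = sum(x$verdict == "regular"),
    frac_rejected = mean(x$verdict != "consistent"))
}

#' Tidy a frame-wise dispersion report
#'
#' @param x A `dispersion_report` object.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @method tidy dispersion_report
#' @export
tidy.dispersion_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dispersion_report")
  tibble::as_tibble(out)
}

#' One-row summary of a frame-wise dispersion report
#'
#' @param x A `dispersion_report` object.
#' @param ... Unused.
#' @return A one-row tibble: frame count, axes, scale range, per-test
#'   `alpha`, and the per-axis fraction of clustered verdicts.
#' @method glance dispersion_report
#' @export
glance.dispersion_report <- function(x, ...) {
  defined <- x[x$verdict != "undefined", ]
  frac <- function(axis) {
    v <- defined$verdict[defined$axis == axis]
    if (length(v) == 0) NA_real_ else mean(v == "clustered")
  }
  tibble::tibble(
    n_frames = length(unique(x$time)),
    axes = paste(sort(unique(x$axis)), collapse = ","),
    k_min = min(x$k), k_max = max(x$k),
    alpha = if (!is.null(attr(x, "alpha"))) attr(x, "alpha") else NA_real_,
    frac_clustered_cross = frac("cross"),
    frac_clustered_long = frac("long"))
}
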