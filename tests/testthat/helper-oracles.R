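# Independent oracles used across the suite.  Nothing here calls the code
# paths it checks: the quantile oracle integrates the chi-squared density
# directly, and the dispersion oracle is a two-pass variance computation.

# Chi-squared quantile by numerical inversion of the integrated density
# (the regularized incomplete gamma function), independent of qchisq.
chisq_quantile_oracle <- function(p, df) {
  dens <- function(x) {
    exp((df / 2 - 1) * log(x) - x / 2 - (df / 2) * log(2) - lgamma(df / 2))
  }
  cdf <- function(q) {
    stats::integrate(dens, 0, q, rel.tol = 1e-12, abs.tol = 1e-14,
                     subdivisions = 500L)$value
  }
  stats::uniroot(function(q) cdf(q) - p, lower = 1e-12, upper = 400,
                 tol = 1e-10)$root
}

# Two-pass variance-to-mean dispersion statistic.
dispersion_oracle <- function(counts) {
  k <- length(counts)
  m <- sum(counts) / k
  s2 <- sum((counts - m)^2) / (k - 1)
  (k - 1) * s2 / m
}

# Build a frame-series tibble from a list of per-frame coordinate matrices.
make_series <- function(frames, dt = 1) {
  purrr::imap(frames, function(m, i) {
    if (is.null(m) || nrow(m) == 0) {
      tibble::tibble(frame = as.integer(i), time = (i - 1) * dt,
                     x = NA_real_, y = NA_real_)
    } else {
      tibble::tibble(frame = as.integer(i), time = (i - 1) * dt,
                     x = m[, 1], y = m[, 2])
    }
  }) |> dplyr::bind_rows()
}

# Uniform field of exactly n points on [0,1]^2.
uniform_frame <- function(n) matrix(stats::runif(2 * n), ncol = 2)
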