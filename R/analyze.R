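#' Frame-wise multiscale dispersion analysis of a tracked experiment
#'
#' For every observation frame and every requested axis, extracts the 1-D
#' coordinate marginal and runs the multiscale dispersion-index sweep;
#' optionally adds the cross-axis chemotactic index of the loaded band.
#' This is the tabular twin of dispersion-index-versus-time plots: one row
#' per (frame, axis, k), ordered by time, then axis, then k.
#'
#' Empty frames yield rows with `statistic = NA` and verdict `"undefined"`
#' rather than being silently dropped.  Frames with fewer than
#' `2 * max(k_range)` points are analysed but reported in a single warning,
#' since sparse counts make the chi-squared approximation unreliable.
#'
#' @param positions A frame series tibble with columns `frame`, `time`,
#'   `x`, `y` (coordinates in `[0, 1]`), as produced by [read_positions()]
#'   or [simulate_chemotaxis()].
#' @param k_range Strictly increasing integers `>= 2`; partition scales.
#' @param alpha Per-test type-I error probability.  No multiple-testing
#'   correction is applied across scales or frames; `alpha` is reported in
#'   every row.
#' @param axes Which coordinate marginals to analyse, a subset of
#'   `c("cross", "long")`.
#' @param band The loaded central band `c(a, b)` for the chemotactic index.
#' @param compute_chemotactic_index Add the cross-axis chemotactic index to
#'   cross-axis rows (`NA` elsewhere)?
#' @return A tibble of class `dispersion_report` with columns `time`,
#'   `axis`, `k`, `statistic`, `lower`, `upper`, `verdict`, `n`,
#'   `chemotactic_index`.
#' @examples
#' frames <- simulate_chemotaxis(scenario("control", n_steps = 400))
#' analyze_frames(frames, k_range = 5:10)
#' @export
analyze_frames <- function(positions, k_range = 5:25, alpha = 0.05,
                           axes = c("cross", "long"),
                           band = c(1 / 3, 2 / 3),
                           compute_chemotactic_index = TRUE) {
  stopifnot(is.data.frame(positions))
  if (!all(c("frame", "time", "x", "y") %in% names(positions))) {
    stop("`positions` must have columns frame, time, x, y", call. = FALSE)
  }
  if (nrow(positions) == 0) stop("`positions` is empty", call. = FALSE)
  axes <- match.arg(axes, several.ok = TRUE)
  if (length(k_range) == 0 || any(k_range < 2)) {
    stop("`k_range` must be non-empty with every k >= 2", call. = FALSE)
  }
  if (is.unsorted(k_range, strictly = TRUE)) {
    stop("`k_range` must be strictly increasing", call. = FALSE)
  }

  frames <- split(tibble::as_tibble(positions),
                  factor(positions$frame, levels = unique(positions$frame)))
  small <- integer(0)
  rows <- purrr::map(frames, function(fr) {
    pts <- fr[!(is.na(fr$x) & is.na(fr$y)), ]
    n <- nrow(pts)
    if (n > 0 && n < 2 * max(k_range)) small <<- c(small, fr$frame[1])
    ci <- if (compute_chemotactic_index && n > 0) {
      chemotactic_index(pts$x, band)
    } else {
      NA_real_
    }
    purrr::map(axes, function(axis) {
      if (n == 0) {
        b <- vapply(k_range, function(k) dispersion_bounds(alpha, k),
                    numeric(2))
        res <- tibble::tibble(
          k = as.integer(k_range), n = 0L, statistic = NA_real_,
          lower = b["lower", ], upper = b["upper", ], alpha = alpha,
          verdict = "undefined")
      } else {
        res <- multiscale_dispersion(marginal_positions(pts, axis),
                                     k_range, alpha)
      }
      ci_col <- if (axis == "cross") ci else NA_real_
      tibble::tibble(
        time = fr$time[1], axis = axis, k = res$k, statistic = res$statistic,
        lower = res$lower, upper = res$upper, verdict = res$verdict,
        n = res$n, chemotactic_index = ci_col)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (length(small) > 0) {
    warning(sprintf(
      "%d frame(s) have fewer than %d points; chi-squared approximation may be unreliable (frames %s)",
      length(small), 2 * max(k_range),
      paste(utils::head(unique(small), 10), collapse = ", ")),
      call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$time,
                        factor(.data$axis, levels = c("cross", "long")),
                        .data$k)
  structure(out, class = c("dispersion_report", class(out)),
            alpha = alpha, k_range = as.integer(k_range), band = band)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$profile <- unclass(cfg$profile)
  cfg
}

#' Simulate a scenario and analyse it end to end
#'
#' One-command reproduction of a full assay experiment: simulate the named
#' scenario, write the positions file, run [analyze_frames()], write the
#' report, and record a manifest (scenario, seed, full configuration,
#' package version).  All outputs are deterministic for a fixed seed, so two
#' runs produce byte-identical files.
#'
#' @param name `"control"`, `"attractant"` or `"repellent"`.
#' @param overrides Named list of [agent_sim_config()] overrides for the
#'   scenario preset.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the preset seed.
#' @param k_range,alpha Passed to [analyze_frames()].
#' @return Invisibly, a named list with elements `positions`, `report` and
#'   `manifest` (file paths), plus `config` and the in-memory `report_table`.
#' @examples
#' \donttest{
#' res <- run_scenario("control", out_dir = tempfile(), seed = 7)
#' head(res$report_table)
#' }
#' @export
run_scenario <- function(name, overrides = list(), out_dir, seed = NULL,
                         k_range = 5:25, alpha = 0.05) {
  config <- do.call(scenario, c(list(name = name), overrides))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_chemotaxis(config)
  pos_path <- file.path(out_dir, paste0(name, "_positions.csv"))
  write_positions(sim, pos_path)
  report <- analyze_frames(sim, k_range = k_range, alpha = alpha,
                           band = config$profile$band)
  rep_path <- file.path(out_dir, paste0(name, "_report.csv"))
  write_report(report, rep_path)
  man_path <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(list(
    scenario = name, seed = config$seed, config = serialize_config(config),
    k_range = as.integer(k_range), alpha = alpha,
    package = "dispersim",
    version = as.character(utils::packageVersion("dispersim"))),
    man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(positions = pos_path, report = rep_path,
                 manifest = man_path, config = config,
                 report_table = report))
}
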