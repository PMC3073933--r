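# Canonical positions dialect: header `frame,time,x,y`, one organism per
# line, comma or whitespace delimited.  A frame with no organisms is encoded
# as a single line whose x and y fields are empty (or NA): a one-point-per-
# line layout has no other way to state that a frame was observed and empty.

tokenize_line <- function(line, sep) {
  if (sep == ",") {
    trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  } else {
    strsplit(trimws(line), "[[:space:]]+")[[1]]
  }
}

num_or_na <- function(tok) {
  if (length(tok) == 0 || tok == "" || toupper(tok) == "NA") return(NA_real_)
  suppressWarnings(as.numeric(tok))
}

#' Read a per-frame positions file
#'
#' Reads tracked organism positions in the canonical layout (header
#' `frame,time,x,y`, one organism per line, comma- or whitespace-delimited)
#' and returns them as a tidy frame series.  Headerless files are accepted
#' through `col_map`.  Coordinates are normalised onto the unit square with
#' `bounds`; when `bounds` is `NULL` the file is assumed to be normalised
#' already, and any coordinate outside `[0, 1]` is an error.
#'
#' @param path Path to the positions file.
#' @param bounds Optional [region_bounds()] giving the physical channel
#'   extents of the raw coordinates.
#' @param dialect `"auto"` (sniff comma vs whitespace from the first line),
#'   `"csv"`, or `"whitespace"`.
#' @param col_map For headerless files, a named integer vector mapping
#'   column positions, e.g. `c(frame = 1, x = 2, y = 3)`; `time` may be
#'   omitted if `fps` is given.
#' @param fps Frame rate used to derive timestamps as
#'   `(frame - min(frame)) / fps` when the file has no time column.
#' @return A tibble with columns `frame` (integer), `time` (seconds), `x`
#'   (cross axis) and `y` (long axis), coordinates in `[0, 1]`; empty frames
#'   appear as a single row with `x` and `y` both `NA`.
#' @seealso [write_positions()] for the inverse.
#' @export
read_positions <- function(path, bounds = NULL,
                           dialect = c("auto", "csv", "whitespace"),
                           col_map = NULL, fps = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) stop(sprintf("empty positions file: %s", path),
                              call. = FALSE)
  sep <- if (dialect == "csv") "," else if (dialect == "whitespace") " "
  else if (grepl(",", lines[keep[1]], fixed = TRUE)) "," else " "

  first <- tokenize_line(lines[keep[1]], sep)
  has_header <- any(is.na(suppressWarnings(as.numeric(first))) &
                      first != "" & toupper(first) != "NA")
  if (has_header) {
    nm <- tolower(first)
    idx <- match(c("frame", "time", "x", "y"), nm)
    names(idx) <- c("frame", "time", "x", "y")
    if (anyNA(idx[c("frame", "x", "y")])) {
      stop("header must name columns frame, x and y (time optional)",
           call. = FALSE)
    }
    data_lines <- keep[-1]
  } else {
    if (is.null(col_map)) col_map <- c(frame = 1, time = 2, x = 3, y = 4)
    idx <- c(frame = unname(col_map["frame"]), time = unname(col_map["time"]),
             x = unname(col_map["x"]), y = unname(col_map["y"]))
    if (anyNA(idx[c("frame", "x", "y")])) {
      stop("`col_map` must map frame, x and y", call. = FALSE)
    }
    data_lines <- keep
  }
  has_time <- !is.na(idx["time"])
  if (!has_time && is.null(fps)) {
    stop("file has no time column: supply `fps` to derive timestamps",
         call. = FALSE)
  }
  if (length(data_lines) == 0) {
    stop(sprintf("no data rows in positions file: %s", path), call. = FALSE)
  }

  n <- length(data_lines)
  frame <- integer(n); time <- numeric(n)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ln <- data_lines[i]
    tok <- tokenize_line(lines[ln], sep)
    need <- max(idx, na.rm = TRUE)
    if (length(tok) < need) {
      # comma dialect: trailing empty fields may be dropped by strsplit
      if (sep == "," && length(tok) >= need - 2) {
        tok <- c(tok, rep("", need - length(tok)))
      } else {
        stop(sprintf("cannot parse line %d of %s: expected %d fields, got %d",
                     ln, path, need, length(tok)), call. = FALSE)
      }
    }
    f <- num_or_na(tok[idx["frame"]])
    if (is.na(f) || f != round(f)) {
      stop(sprintf("cannot parse line %d of %s: bad frame id '%s'",
                   ln, path, tok[idx["frame"]]), call. = FALSE)
    }
    frame[i] <- as.integer(f)
    if (has_time) {
      tv <- num_or_na(tok[idx["time"]])
      if (is.na(tv)) {
        stop(sprintf("cannot parse line %d of %s: bad time '%s'",
                     ln, path, tok[idx["time"]]), call. = FALSE)
      }
      time[i] <- tv
    }
    xv <- num_or_na(tok[idx["x"]]); yv <- num_or_na(tok[idx["y"]])
    if (xor(is.na(xv), is.na(yv))) {
      stop(sprintf("cannot parse line %d of %s: one coordinate missing",
                   ln, path), call. = FALSE)
    }
    xs[i] <- xv; ys[i] <- yv
  }
  if (!has_time) time <- (frame - min(frame)) / fps

  # range check with file line numbers, then the affine normalisation
  if (is.null(bounds)) bounds <- region_bounds()
  marker <- is.na(xs) & is.na(ys)
  for (axis in c("x", "y")) {
    v <- if (axis == "x") xs else ys
    lo <- bounds[[axis]][1]; hi <- bounds[[axis]][2]
    bad <- which(!marker & (v < lo | v > hi))
    if (length(bad) > 0) {
      stop(sprintf("line %d of %s: %s = %g outside bounds [%g, %g]",
                   data_lines[bad[1]], path, axis, v[bad[1]], lo, hi),
           call. = FALSE)
    }
  }
  out <- normalize_positions(
    tibble::tibble(frame = frame, time = time, x = xs, y = ys), bounds)

  ft <- dplyr::distinct(out, .data$frame, .data$time)
  if (anyDuplicated(ft$frame)) {
    stop("inconsistent timestamps: a frame id maps to several times",
         call. = FALSE)
  }
  ft <- ft[order(ft$frame), ]
  if (is.unsorted(ft$time, strictly = TRUE)) {
    stop("non-monotone times: timestamps must increase strictly with frame id",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$frame)
}

fmt_num <- function(v) {
  ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
}

#' Write a frame series in the canonical positions layout
#'
#' Writes `frame,time,x,y` comma-separated with round-trip-exact float
#' formatting: [read_positions()] on the output reproduces the input
#' exactly, including empty frames, and the bytes are deterministic for a
#' given input.
#'
#' @param positions A tibble with columns `frame`, `time`, `x`, `y`
#'   (coordinates already in `[0, 1]`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  stopifnot(is.data.frame(positions))
  if (!all(c("frame", "time", "x", "y") %in% names(positions))) {
    stop("`positions` must have columns frame, time, x, y", call. = FALSE)
  }
  lines <- c("frame,time,x,y",
             sprintf("%d,%s,%s,%s", as.integer(positions$frame),
                     fmt_num(positions$time), fmt_num(positions$x),
                     fmt_num(positions$y)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

report_cols <- c("time", "axis", "k", "statistic", "lower", "upper",
                 "verdict", "n", "chemotactic_index")

#' Write a dispersion report table
#'
#' Long-format delimited text with header
#' `time,axis,k,statistic,lower,upper,verdict,n,chemotactic_index`.
#'
#' @param report A report tibble from [analyze_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  if (!all(report_cols %in% names(report))) {
    stop("`report` is missing required report columns", call. = FALSE)
  }
  df <- as.data.frame(report)[, report_cols]
  num <- function(v) ifelse(is.na(v), "NA",
                            ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
                                   formatC(v, digits = 17, format = "g")))
  lines <- c(paste(report_cols, collapse = ","),
             sprintf("%s,%s,%d,%s,%s,%s,%s,%d,%s",
                     num(df$time), df$axis, as.integer(df$k),
                     num(df$statistic), num(df$lower), num(df$upper),
                     df$verdict, as.integer(df$n), num(df$chemotactic_index)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a dispersion report table written by [write_report()]
#'
#' @param path Path to the report file.
#' @return A tibble of class `dispersion_report`.
#' @export
read_report <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), axis = readr::col_character(),
    k = readr::col_integer(), statistic = readr::col_double(),
    lower = readr::col_double(), upper = readr::col_double(),
    verdict = readr::col_character(), n = readr::col_integer(),
    chemotactic_index = readr::col_double()), progress = FALSE)
  structure(out, class = c("dispersion_report", class(out)))
}

#' Read a key-value configuration file
#'
#' A single YAML file can configure the analysis (`k_range`, `alpha`,
#' `axes`, `band`, `fps`, `bounds`) and the simulator (any
#' [agent_sim_config()] field; `profile` as a nested map).  Unknown keys are
#' an error, so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  known <- c("k_range", "alpha", "axes", "band", "fps", "bounds",
             "compute_chemotactic_index",
             names(formals(agent_sim_config)), "profile")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$k_range)) {
    kr <- cfg$k_range
    if (is.character(kr) && grepl(":", kr)) {
      p <- as.integer(strsplit(kr, ":", fixed = TRUE)[[1]])
      kr <- seq(p[1], p[2])
    }
    cfg$k_range <- as.integer(unlist(kr))
  }
  if (!is.null(cfg$bounds)) {
    b <- cfg$bounds
    # YAML 1.1 reads a bare `y` key as the boolean TRUE; undo that
    names(b)[names(b) %in% c("TRUE", "yes")] <- "y"
    cfg$bounds <- region_bounds(x = as.numeric(b$x), y = as.numeric(b$y))
  }
  if (!is.null(cfg$profile)) {
    cfg$profile <- do.call(chemical_profile, cfg$profile)
  }
  cfg
}
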