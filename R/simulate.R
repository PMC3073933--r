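with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate a homogeneous Poisson point field on the unit interval
#'
#' Draws the point count from a Poisson distribution with the given mean and
#' scatters that many points independently and uniformly on `[0, 1]`.
#'
#' @param intensity Non-negative expected number of points.
#' @param seed Optional integer; when supplied the draw is reproducible and
#'   leaves the global RNG state untouched.
#' @return A numeric vector of positions in `[0, 1]`.
#' @examples
#' simulate_homogeneous_poisson(200, seed = 1)
#' @export
simulate_homogeneous_poisson <- function(intensity, seed = NULL) {
  if (!is.numeric(intensity) || length(intensity) != 1 || is.na(intensity) ||
      intensity < 0) {
    stop("`intensity` must be a single non-negative number", call. = FALSE)
  }
  with_seed_maybe(seed, {
    n <- stats::rpois(1, intensity)
    stats::runif(n)
  })
}

#' Simulate an inhomogeneous Poisson point field by thinning
#'
#' Generates candidates from a homogeneous process at the dominating rate
#' `lambda_max` and retains the candidate at position `x` with probability
#' `intensity_fn(x) / lambda_max` (Lewis-Shedler thinning).  The result is a
#' Poisson process whose expected count in any set `B` is
#' \eqn{\int_B \lambda(x)\,dx}.
#'
#' @param intensity_fn Vectorised function on `[0, 1]` returning non-negative
#'   intensities bounded by `lambda_max`.
#' @param lambda_max Finite upper bound of `intensity_fn` on `[0, 1]`.
#' @param seed Optional integer for a reproducible draw.
#' @return A numeric vector of positions in `[0, 1]`.
#' @examples
#' # intensity 600 on the central third, zero elsewhere: ~200 points expected
#' f <- function(x) 600 * (x >= 1 / 3 & x < 2 / 3)
#' simulate_inhomogeneous_poisson(f, lambda_max = 600, seed = 1)
#' @export
simulate_inhomogeneous_poisson <- function(intensity_fn, lambda_max,
                                           seed = NULL) {
  stopifnot(is.function(intensity_fn))
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      !is.finite(lambda_max) || lambda_max < 0) {
    stop("`lambda_max` must be a single finite non-negative number",
         call. = FALSE)
  }
  with_seed_maybe(seed, {
    n_cand <- stats::rpois(1, lambda_max)
    cand <- stats::runif(n_cand)
    if (n_cand == 0) return(numeric(0))
    lam <- intensity_fn(cand)
    if (!is.numeric(lam) || length(lam) != n_cand || anyNA(lam)) {
      stop("`intensity_fn` must return one finite value per position",
           call. = FALSE)
    }
    if (any(lam < 0)) {
      stop("`intensity_fn` returned a negative intensity", call. = FALSE)
    }
    if (any(lam > lambda_max * (1 + 1e-12))) {
      stop("`intensity_fn` exceeds `lambda_max` at a sampled point",
           call. = FALSE)
    }
    cand[stats::runif(n_cand) < lam / lambda_max]
  })
}

#' Static chemical landscape of a band-loaded channel
#'
#' The loaded central band is modelled as a smoothed indicator with Gaussian
#' (error-function) edges of width `sigma`, scaled so the concentration at
#' the band centre equals `amplitude` for every `sigma`.  The gradient is the
#' analytic derivative of this profile, so the simulator never differentiates
#' numerically.  `sigma = 0` degenerates to the sharp indicator; its gradient
#' is taken as 0 everywhere, including on the (measure-zero) edges.
#'
#' `sigma_growth` (unit/s, default 0) lets the edges blur linearly in time,
#' a phenomenological stand-in for slow lateral diffusion of the chemical
#' after the flow stops; the profile is static by default.
#'
#' @param band Numeric `c(a, b)` within `[0, 1]`, the loaded band; default
#'   the central third.
#' @param sigma Edge-smoothing length in unit-interval units, `>= 0`.
#' @param amplitude Peak concentration, `> 0` (arbitrary concentration
#'   units; only the product with the chemotactic sensitivity matters).
#' @param sigma_growth Linear growth rate of `sigma` with time, `>= 0`.
#' @return An object of class `chemical_profile`.
#' @examples
#' chemical_profile(sigma = 0.05)
#' @export
chemical_profile <- function(band = c(1 / 3, 2 / 3), sigma = 0.1,
                             amplitude = 1, sigma_growth = 0) {
  if (length(band) != 2 || anyNA(band) || band[1] >= band[2] ||
      band[1] < 0 || band[2] > 1) {
    stop("`band` must be c(a, b) with 0 <= a < b <= 1", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (sigma_growth < 0) stop("`sigma_growth` must be >= 0", call. = FALSE)
  structure(list(band = as.numeric(band), sigma = as.numeric(sigma),
                 amplitude = as.numeric(amplitude),
                 sigma_growth = as.numeric(sigma_growth)),
            class = "chemical_profile")
}

#' @export
print.chemical_profile <- function(x, ...) {
  cat(sprintf(
    "<chemical_profile> band [%g, %g], sigma %g, amplitude %g%s\n",
    x$band[1], x$band[2], x$sigma, x$amplitude,
    if (x$sigma_growth > 0) sprintf(", sigma growth %g/s", x$sigma_growth)
    else ""))
  invisible(x)
}

# Unchecked evaluation used in the inner simulation loop.
profile_eval <- function(profile, x, t = 0) {
  a <- profile$band[1]; b <- profile$band[2]
  s <- profile$sigma + profile$sigma_growth * t
  amp <- profile$amplitude
  if (s == 0) {
    return(list(concentration = amp * as.numeric(x >= a & x <= b),
                gradient = rep(0, length(x))))
  }
  centre <- (a + b) / 2
  norm <- stats::pnorm((centre - a) / s) - stats::pnorm((centre - b) / s)
  conc <- amp * (stats::pnorm((x - a) / s) - stats::pnorm((x - b) / s)) / norm
  grad <- amp * (stats::dnorm((x - a) / s) - stats::dnorm((x - b) / s)) /
    (s * norm)
  list(concentration = conc, gradient = grad)
}

#' Evaluate a chemical profile and its gradient
#'
#' @param profile A [chemical_profile()].
#' @param x Cross-axis positions in `[0, 1]` (vectorised).
#' @param t Time in seconds (affects the profile only when `sigma_growth`
#'   is positive).
#' @return A tibble with columns `x`, `concentration`, `gradient`.
#' @examples
#' chemical_profile_value(chemical_profile(), c(0.1, 0.5, 0.9))
#' @export
chemical_profile_value <- function(profile, x, t = 0) {
  if (!inherits(profile, "chemical_profile")) {
    stop("`profile` must be a chemical_profile object", call. = FALSE)
  }
  check_unit_positions(x)
  v <- profile_eval(profile, x, t)
  tibble::tibble(x = x, concentration = v$concentration,
                 gradient = v$gradient)
}

#' Configuration of the agent-based chemotaxis simulator
#'
#' Parameterises a biased random walk that is the agent-level analogue of
#' the Keller-Segel drift-diffusion model: per time step each agent's
#' cross-axis position gains a deterministic drift
#' \eqn{\chi\,\partial c/\partial x\,\Delta t} along the chemical gradient
#' plus a mean-zero Gaussian increment of variance \eqn{2 D \Delta t}; the
#' long-axis position performs the diffusion alone.  Both axes reflect off
#' the channel walls at 0 and 1.
#'
#' @param n_agents Number of organisms, `> 0` (default 200, the typical
#'   per-frame count in the assay being emulated).
#' @param diffusion Effective diffusivity `D` in squared channel widths per
#'   second, `>= 0` (0 freezes the random motility, useful for testing
#'   drift alone).  The default `8e-4` lets a middle-third release
#'   homogenise over some tens of seconds, matching control behaviour.
#' @param sensitivity Chemotactic sensitivity `chi` in unit^2/s per
#'   concentration unit; `> 0` for an attractant, `< 0` for a repellent,
#'   `0` for a control.
#' @param dt Time step in seconds, `> 0`.
#' @param n_steps Number of steps, `> 0`; `dt * n_steps` is the simulated
#'   horizon.
#' @param frame_stride Emit an observation frame every this many steps
#'   (`<= n_steps`); a frame is also emitted at time 0.
#' @param profile A [chemical_profile()].
#' @param init Initial placement of the cross coordinate: `"uniform"`,
#'   `"middle_third"` (agents released in the central band, as in the
#'   control experiment), or `"lateral_bands"` (agents start in the two side
#'   sections, as when the chemical occupies the centre at injection).
#'   The long coordinate is always uniform.
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @param wall_attraction Magnitude (unit/s) of an optional short-range
#'   drift toward the nearest wall on the cross axis, a phenomenological
#'   knob for wall-drag accumulation; default 0 (off).
#' @param wall_range Distance from a wall within which `wall_attraction`
#'   acts.
#' @return An object of class `agent_sim_config`.
#' @seealso [scenario()] for presets, [simulate_chemotaxis()] to run.
#' @export
agent_sim_config <- function(n_agents = 200, diffusion = 8e-4,
                             sensitivity = 0, dt = 0.05, n_steps = 2400,
                             frame_stride = 100,
                             profile = chemical_profile(),
                             init = c("uniform", "middle_third",
                                      "lateral_bands"),
                             seed = 1, wall_attraction = 0,
                             wall_range = 0.05) {
  init <- match.arg(init)
  if (n_agents <= 0 || n_agents != round(n_agents)) {
    stop("`n_agents` must be a positive integer", call. = FALSE)
  }
  if (diffusion < 0) stop("`diffusion` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (n_steps <= 0 || n_steps != round(n_steps)) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  if (frame_stride <= 0 || frame_stride != round(frame_stride)) {
    stop("`frame_stride` must be a positive integer", call. = FALSE)
  }
  if (frame_stride > n_steps) {
    stop("`frame_stride` must not exceed `n_steps`", call. = FALSE)
  }
  if (!inherits(profile, "chemical_profile")) {
    stop("`profile` must be a chemical_profile object", call. = FALSE)
  }
  if (wall_attraction < 0) stop("`wall_attraction` must be >= 0", call. = FALSE)
  structure(list(
    n_agents = as.integer(n_agents), diffusion = diffusion,
    sensitivity = sensitivity, dt = dt, n_steps = as.integer(n_steps),
    frame_stride = as.integer(frame_stride), profile = profile, init = init,
    seed = as.integer(seed), wall_attraction = wall_attraction,
    wall_range = wall_range), class = "agent_sim_config")
}

#' @export
print.agent_sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<agent_sim_config> %d agents, D = %g, chi = %g, dt = %g s, ",
           "%d steps (%.1f s), frame every %d steps, init %s, seed %d\n"),
    x$n_agents, x$diffusion, x$sensitivity, x$dt, x$n_steps,
    x$dt * x$n_steps, x$frame_stride, x$init, x$seed))
  print(x$profile)
  invisible(x)
}

#' Preset simulator configurations for the three assay scenarios
#'
#' `"control"`: no chemical (`sensitivity = 0`), organisms released in the
#' middle third and left to disperse.  `"attractant"`: organisms injected
#' over the whole width, central band loaded with an attractant
#' (`sensitivity > 0`).  `"repellent"`: the same geometry with a repellent
#' (`sensitivity < 0`).  All presets use 200 agents and a 2-minute horizon
#' with a frame every 5 s; any [agent_sim_config()] field can be overridden
#' through `...`.
#'
#' @param name `"control"`, `"attractant"` or `"repellent"`.
#' @param ... Overrides merged on top of the preset, passed to
#'   [agent_sim_config()].
#' @return An [agent_sim_config()] object.
#' @examples
#' scenario("control")
#' scenario("attractant", n_agents = 500)
#' @export
scenario <- function(name = c("control", "attractant", "repellent"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    control = list(sensitivity = 0, init = "middle_third"),
    attractant = list(sensitivity = 3e-3, init = "uniform"),
    repellent = list(sensitivity = -3e-3, init = "uniform"))
  overrides <- list(...)
  do.call(agent_sim_config, utils::modifyList(preset, overrides))
}

reflect01 <- function(x) {
  y <- x %% 2
  ifelse(y > 1, 2 - y, y)
}

init_positions <- function(n, init) {
  switch(init,
    uniform = stats::runif(n),
    middle_third = stats::runif(n, 1 / 3, 2 / 3),
    lateral_bands = {
      side <- stats::runif(n) < 0.5
      ifelse(side, stats::runif(n, 0, 1 / 3), stats::runif(n, 2 / 3, 1))
    })
}

#' Run the agent-based chemotaxis simulation
#'
#' Euler-Maruyama integration of the biased random walk described in
#' [agent_sim_config()], with reflecting walls.  All agents advance together
#' in one vectorised update per step, so the trajectory is deterministic
#' given the seed and independent of any agent ordering.  An observation
#' frame (all agent positions) is recorded at time 0 and every
#' `frame_stride` steps thereafter.
#'
#' @param config An [agent_sim_config()], usually from [scenario()].
#' @return A tibble with columns `frame` (1-based), `time` (seconds), `x`
#'   (cross axis) and `y` (long axis), all positions in `[0, 1]`; the
#'   configuration is attached as attribute `"config"`.
#' @examples
#' frames <- simulate_chemotaxis(scenario("control", n_steps = 200))
#' dplyr::count(frames, frame, time)
#' @export
simulate_chemotaxis <- function(config) {
  if (!inherits(config, "agent_sim_config")) {
    stop("`config` must be an agent_sim_config object", call. = FALSE)
  }
  n <- config$n_agents
  sd_step <- sqrt(2 * config$diffusion * config$dt)
  chi_dt <- config$sensitivity * config$dt
  wall_on <- config$wall_attraction > 0
  n_frames <- config$n_steps %/% config$frame_stride + 1L
  with_seed_maybe(config$seed, {
    cross <- init_positions(n, config$init)
    long <- stats::runif(n)
    xs <- matrix(NA_real_, nrow = n, ncol = n_frames)
    ys <- matrix(NA_real_, nrow = n, ncol = n_frames)
    times <- numeric(n_frames)
    xs[, 1] <- cross; ys[, 1] <- long
    fi <- 1L
    for (step in seq_len(config$n_steps)) {
      t_now <- (step - 1L) * config$dt
      drift <- 0
      if (chi_dt != 0) {
        g <- profile_eval(config$profile, cross, t_now)$gradient
        drift <- chi_dt * g
      }
      if (wall_on) {
        towards_wall <- (cross > 1 - config$wall_range) -
          (cross < config$wall_range)
        drift <- drift + config$wall_attraction * config$dt * towards_wall
      }
      cross <- reflect01(cross + drift + stats::rnorm(n, 0, sd_step))
      long <- reflect01(long + stats::rnorm(n, 0, sd_step))
      if (step %% config$frame_stride == 0L) {
        fi <- fi + 1L
        xs[, fi] <- cross; ys[, fi] <- long
        times[fi] <- step * config$dt
      }
    }
    out <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = n),
      time = rep(times, each = n),
      x = as.vector(xs), y = as.vector(ys))
    attr(out, "config") <- config
    out
  })
}
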