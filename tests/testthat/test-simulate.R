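test_that("homogeneous Poisson generator is seeded and calibrated", {
  expect_length(simulate_homogeneous_poisson(0, seed = 1), 0)
  expect_identical(simulate_homogeneous_poisson(200, seed = 9),
                   simulate_homogeneous_poisson(200, seed = 9))
  expect_error(simulate_homogeneous_poisson(-3), "non-negative")
  withr::with_seed(17, {
    counts <- replicate(1000, length(simulate_homogeneous_poisson(200)))
  })
  # Poisson(200): mean 200, sd of the 1000-replicate mean = sqrt(0.2)
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(0.2))
  expect_true(all(vapply(
    list(simulate_homogeneous_poisson(150, seed = 2)),
    function(x) all(x >= 0 & x <= 1), logical(1))))
})

test_that("thinning with constant intensity matches the homogeneous law", {
  withr::with_seed(23, {
    n_hom <- replicate(1000, length(simulate_homogeneous_poisson(120)))
    n_thin <- replicate(1000, length(
      simulate_inhomogeneous_poisson(function(x) rep(120, length(x)), 120)))
  })
  se <- sqrt(stats::var(n_hom) / 1000 + stats::var(n_thin) / 1000)
  expect_lt(abs(mean(n_hom) - mean(n_thin)), 3 * se)
})

test_that("thinning realises a central-third intensity function", {
  f <- function(x) 600 * (x >= 1 / 3 & x < 2 / 3)
  withr::with_seed(29, {
    fields <- replicate(200, simulate_inhomogeneous_poisson(f, 600),
                        simplify = FALSE)
  })
  n_in <- vapply(fields, function(x) count_in_interval(x, c(1 / 3, 2 / 3)),
                 integer(1))
  n_out <- vapply(fields, length, integer(1)) - n_in
  expect_lt(abs(mean(n_in) - 200), 3 * sqrt(200 / 200))
  expect_identical(sum(n_out), 0L)
  expect_length(simulate_inhomogeneous_poisson(function(x) 0 * x, 10,
                                               seed = 1), 0)
  expect_error(
    simulate_inhomogeneous_poisson(function(x) -x, 10, seed = 1),
    "negative")
  expect_error(
    simulate_inhomogeneous_poisson(function(x) rep(20, length(x)), 10,
                                   seed = 1),
    "exceeds")
})

test_that("chemical profile peaks at amplitude with a symmetric gradient", {
  for (sigma in c(0.02, 0.1, 0.5)) {
    p <- chemical_profile(sigma = sigma, amplitude = 2.5)
    centre <- chemical_profile_value(p, 0.5)
    expect_equal(centre$concentration, 2.5, tolerance = 1e-12)
    expect_equal(centre$gradient, 0, tolerance = 1e-12)
    d <- 0.13
    v <- chemical_profile_value(p, c(0.5 - d, 0.5 + d))
    expect_equal(v$gradient[2], -v$gradient[1], tolerance = 1e-12)
    expect_equal(v$concentration[2], v$concentration[1], tolerance = 1e-12)
  }
  # far outside a narrow-edged band the concentration vanishes
  p <- chemical_profile(sigma = 0.02)
  expect_lt(chemical_profile_value(p, 0.01)$concentration, 1e-10)
  # sigma = 0 degenerates to the sharp indicator with zero gradient
  p0 <- chemical_profile(sigma = 0)
  v0 <- chemical_profile_value(p0, c(0.1, 0.5, 1 / 3))
  expect_equal(v0$concentration, c(0, 1, 1))
  expect_equal(v0$gradient, c(0, 0, 0))
  expect_error(chemical_profile_value(p0, 1.2), "\\[0, 1\\]")
})

test_that("scenario presets encode the three experiments and merge overrides", {
  expect_identical(scenario("control")$sensitivity, 0)
  expect_identical(scenario("control")$init, "middle_third")
  expect_gt(scenario("attractant")$sensitivity, 0)
  expect_identical(scenario("attractant")$init, "uniform")
  expect_lt(scenario("repellent")$sensitivity, 0)
  cfg <- scenario("attractant", n_agents = 500)
  expect_identical(cfg$n_agents, 500L)
  expect_identical(cfg$dt, scenario("attractant")$dt)
  expect_equal(cfg$dt * cfg$n_steps, 120)
  expect_error(scenario("mystery"), "arg")
})

test_that("simulator conserves agents, stays in the unit square, is seeded", {
  cfg <- scenario("attractant", n_agents = 80, n_steps = 300,
                  frame_stride = 60, seed = 31)
  sim <- simulate_chemotaxis(cfg)
  expect_identical(as.integer(table(sim$frame)),
                   rep(80L, 300 %/% 60 + 1))
  expect_true(all(sim$x >= 0 & sim$x <= 1 & sim$y >= 0 & sim$y <= 1))
  expect_equal(unique(sim$time), seq(0, 15, by = 3))
  expect_identical(sim, simulate_chemotaxis(cfg))
})

test_that("frozen dynamics keep every frame at the initial placement", {
  cfg <- agent_sim_config(n_agents = 40, diffusion = 0, sensitivity = 0,
                          n_steps = 100, frame_stride = 25, seed = 3)
  sim <- simulate_chemotaxis(cfg)
  first <- sim[sim$frame == 1, c("x", "y")]
  for (f in unique(sim$frame)) {
    expect_identical(sim[sim$frame == f, c("x", "y")], first)
  }
})

test_that("control-like runs homogenise from a middle-third release", {
  withr::with_seed(37, seeds <- sample.int(1e6, 40))
  drop <- vapply(seeds, function(s) {
    sim <- simulate_chemotaxis(scenario("control", seed = s, n_steps = 1200,
                                        frame_stride = 1200))
    i0 <- dispersion_test(sim$x[sim$frame == 1], 10)$statistic
    i1 <- dispersion_test(sim$x[sim$frame == 2], 10)$statistic
    i1 < i0
  }, logical(1))
  expect_gte(mean(drop), 0.9)
})

test_that("mean-squared displacement grows like 2 D t before wall effects", {
  # t = 10 s, D = 8e-4: sqrt(2 D t) = 0.126 << 0.2, agents start centrally
  cfg <- agent_sim_config(n_agents = 4000, diffusion = 8e-4,
                          sensitivity = 0, dt = 0.05, n_steps = 200,
                          frame_stride = 200, init = "middle_third",
                          seed = 41)
  sim <- simulate_chemotaxis(cfg)
  x0 <- sim$x[sim$frame == 1]
  x1 <- sim$x[sim$frame == 2]
  msd <- mean((x1 - x0)^2)
  expect_lt(abs(msd - 2 * 8e-4 * 10) / (2 * 8e-4 * 10), 0.10)
})

test_that("attractant and repellent with equal |chi| are mirror experiments", {
  withr::with_seed(43, seeds <- sample.int(1e6, 60))
  frac_in <- function(x) mean(x >= 1 / 3 & x < 2 / 3)
  runs <- purrr::map(seeds, function(s) {
    att <- simulate_chemotaxis(scenario("attractant", seed = s,
                                        n_steps = 1200, frame_stride = 200))
    rep_ <- simulate_chemotaxis(scenario("repellent", seed = s,
                                         n_steps = 1200, frame_stride = 200))
    list(att = vapply(split(att$x, att$frame), frac_in, numeric(1)),
         rep = vapply(split(rep_$x, rep_$frame), frac_in, numeric(1)))
  })
  att_mean <- colMeans(do.call(rbind, purrr::map(runs, "att")))
  rep_mean <- colMeans(do.call(rbind, purrr::map(runs, "rep")))
  expect_true(all(diff(att_mean) > 0))
  expect_true(all(diff(rep_mean) < 0))
})

test_that("with chi = 0 the simulator's null matches the test's null", {
  # 1000 independent short runs; the final frame of each is a fresh
  # 200-agent uniform field, so the frame-tests are independent
  withr::with_seed(47, seeds <- sample.int(1e6, 1000))
  rejected <- vapply(seeds, function(s) {
    cfg <- scenario("control", init = "uniform", seed = s, n_steps = 100,
                    frame_stride = 100)
    sim <- simulate_chemotaxis(cfg)
    dispersion_test(sim$x[sim$frame == 2], 10, 0.05)$verdict != "consistent"
  }, logical(1))
  expect_gte(mean(rejected), 0.03)
  expect_lte(mean(rejected), 0.07)
})

test_that("simulator configuration is validated", {
  expect_error(agent_sim_config(dt = 0), "dt")
  expect_error(agent_sim_config(n_steps = 0), "n_steps")
  expect_error(agent_sim_config(n_steps = 10, frame_stride = 11),
               "frame_stride")
  expect_error(agent_sim_config(n_agents = 0), "n_agents")
  expect_error(agent_sim_config(profile = list(band = c(0, 1))), "profile")
})
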