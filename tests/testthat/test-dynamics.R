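test_that("kinetic temperature is m<v^2>/3 over free beads", {
  geom <- free_space_geometry()
  st <- system_state(rbind(c(0, 0, -3), c(1, 0, -3)), geometry = geom)
  expect_equal(kinetic_temperature(st, sim_params(N = 2)), 0)
  st$velocities <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_equal(kinetic_temperature(st, sim_params(N = 2)), 1)
  st$tether <- 1L
  expect_equal(kinetic_temperature(st, sim_params(N = 2)), 1)
})

test_that("without friction and noise the integrator conserves energy", {
  p <- sim_params(N = 2, F = 0, rho = 0, friction = 0, dt = 0.005)
  geom <- free_space_geometry(p)
  st <- system_state(rbind(c(0, 0, -3), c(0, 0, -4.3)), geometry = geom)
  energy_of <- function(s) {
    f <- total_forces(s, p, field_on = FALSE)
    attr(f, "energy") + 0.5 * p$mass * sum(s$velocities^2)
  }
  e0 <- energy_of(st)
  expect_gt(e0, 0) # bond stretched to 1.3 sigma stores energy
  drift_at <- function(dt) {
    q <- p
    q$dt <- dt
    s <- st
    drift <- 0
    for (k in 1:10) {
      s <- langevin_run(s, q, round(50 / dt / 10), seed = 1, index = k,
                        field_on = FALSE)
      drift <- max(drift, abs(energy_of(s) - e0))
    }
    drift
  }
  d1 <- drift_at(0.005)
  expect_lt(d1 / e0, 5e-3)
  # second-order scheme: quartering the step cuts the error ~16x
  d2 <- drift_at(0.00125)
  expect_lt(d2, d1 / 4)
})

test_that("a free bead equilibrates to the thermostat temperature", {
  p <- sim_params(N = 2)
  geom <- free_space_geometry(p)
  st <- system_state(rbind(c(0, 0, 0)), geometry = geom)
  out <- langevin_run(st, p, 4e5, seed = 21, index = 0, field_on = FALSE,
                      record_every = 400)
  temps <- attr(out, "temp_trace")[-(1:50)] # drop the v = 0 transient
  tbar <- mean(temps)
  se <- sd(temps) / sqrt(length(temps))
  expect_lt(abs(tbar - p$kBT), 3 * se + 0.02)
})

test_that("stationary velocities are Maxwell-Boltzmann and isotropic", {
  p <- sim_params(N = 2)
  geom <- free_space_geometry(p)
  st <- system_state(rbind(c(0, 0, 0)), geometry = geom)
  st <- langevin_run(st, p, 2000, seed = 31, index = 0, field_on = FALSE)
  vs <- matrix(NA_real_, 400, 3)
  for (k in seq_len(nrow(vs))) {
    st <- langevin_run(st, p, 600, seed = 31, index = k, field_on = FALSE)
    vs[k, ] <- st$velocities[1, ]
  }
  ks <- stats::ks.test(vs[, 1], "pnorm", 0, sqrt(p$kBT / p$mass))
  expect_gt(ks$p.value, 0.01)
  # equal variance in the three components within sampling error
  v <- apply(vs, 2, var)
  expect_lt(max(v) / min(v), 1.6) # F(399,399) 3-sigma-ish bound
  expect_lt(abs(mean(vs)), 0.1)
})

test_that("free diffusion follows the Einstein relation D = kBT/xi", {
  p <- sim_params(N = 2)
  geom <- free_space_geometry(p)
  d_theory <- p$kBT / p$friction
  tau_v <- p$mass / p$friction
  t_obs <- 20
  n_walk <- 1500
  disp2 <- numeric(n_walk)
  for (k in seq_len(n_walk)) {
    st <- system_state(rbind(c(0, 0, 0)), geometry = geom)
    # thermalise velocities first so the start is stationary
    st <- langevin_run(st, p, 1000, seed = 77, index = k, field_on = FALSE)
    x0 <- st$positions[1, ]
    st <- langevin_run(st, p, t_obs / p$dt, seed = 78, index = k,
                       field_on = FALSE)
    disp2[k] <- sum((st$positions[1, ] - x0)^2)
  }
  # stationary Ornstein-Uhlenbeck MSD with inertial correction
  msd_theory <- 6 * d_theory * (t_obs - tau_v * (1 - exp(-t_obs / tau_v)))
  ratio <- mean(disp2) / msd_theory
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("trajectories are bit-identical under a fixed seed", {
  p <- sim_params(N = 8, F = 20, rho = 0.2, seed = 5)
  geom <- build_channel(p)
  obst <- place_obstacles(p$rho, geom, p, seed = 5)
  st <- init_chain(p, geom, obst, seed = 5)
  a <- langevin_run(st, p, 500, seed = 5, index = 1)
  b <- langevin_run(st, p, 500, seed = 5, index = 1)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c <- langevin_run(st, p, 500, seed = 5, index = 2)
  expect_false(identical(a$positions, c$positions))
})

test_that("trajectory frames can be dumped and written as XYZ", {
  p <- sim_params(N = 6, F = 0, rho = 0)
  geom <- free_space_geometry(p)
  st <- system_state(cbind(0, 0, -(0:5)), geometry = geom)
  out <- langevin_run(st, p, 1000, seed = 9, index = 0, field_on = FALSE,
                      dump_every = 250)
  frames <- attr(out, "frames")
  expect_length(frames, 4)
  expect_equal(attr(out, "frame_times"), (1:4) * 250 * p$dt)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(frames, path, times = attr(out, "frame_times"))
  back <- read_trajectory(path)
  expect_length(back, 4)
  expect_equal(back[[4]]$positions, round(frames[[4]], 6),
               ignore_attr = TRUE)
})

test_that("equilibrate preserves the tether and relaxes the chain", {
  p <- sim_params(N = 16, F = 10, rho = 0, n_equil = 8000, seed = 13)
  geom <- build_channel(p)
  st <- init_chain(p, geom, NULL, seed = 13)
  expect_identical(equilibrate(st, p, n_steps = 0), st)
  out <- equilibrate(st, p, seed = 13, check_convergence = FALSE)
  # bead 1 stays pinned at the entrance
  expect_identical(out$positions[1, ], c(0, 0, 0))
  # the rest of the chain stays on the cis side of the membrane
  expect_true(all(out$positions[-1, 3] < 1))
  expect_gt(length(attr(out, "rg2_trace")), 10)
  # kinetic temperature near the thermostat value
  tk <- kinetic_temperature(out, p)
  expect_lt(abs(tk - p$kBT) / p$kBT, 0.25)
})

test_that("equilibrated free chains swell like self-avoiding walks", {
  p <- sim_params(N = 2)
  geom <- free_space_geometry(p)
  mean_rg2 <- function(n, seed) {
    pos <- cbind(0, 0, -(seq_len(n) - 1) * 0.97)
    st <- system_state(pos, geometry = geom)
    st <- langevin_run(st, p, 3e4, seed = seed, index = 0, field_on = FALSE)
    out <- langevin_run(st, p, 9e4, seed = seed, index = 1,
                        field_on = FALSE, record_every = 300)
    mean(attr(out, "rg2_trace"))
  }
  ns <- c(16, 32, 64)
  rg2 <- vapply(seq_along(ns), function(i) mean_rg2(ns[i], 40 + i), 0)
  # Rg^2 must grow faster than the ideal-chain linear law across N
  slope <- coef(lm(log(rg2) ~ log(ns)))[2]
  expect_gt(slope, 1.05)
  expect_lt(slope, 1.5)
})
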