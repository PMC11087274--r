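test_that("Maxwell-Boltzmann velocities have the right moments", {
  expect_equal(maxwell_boltzmann_velocities(rep("C", 5), 0), matrix(0, 5, 3))
  set.seed(3)
  sp <- rep(c("C", "H", "O", "N"), 16)
  m <- atomic_masses(sp)
  # mean kinetic energy over many draws: (3/2) N k_B T
  ke <- replicate(1000, {
    v <- maxwell_boltzmann_velocities(sp, 300, remove_com = FALSE)
    0.5 * sum(m * rowSums(v^2)) / 4.184e-4
  })
  expect_equal(mean(ke), 1.5 * 64 * NR_KB * 300, tolerance = 0.02)
  # per-species component variance ~ k_B T / m
  vs <- replicate(200, maxwell_boltzmann_velocities(sp, 300, remove_com = FALSE))
  for (el in c("H", "O")) {
    rows <- which(sp == el)
    v2 <- mean(vs[rows, , ]^2)
    expect_equal(v2, NR_KB * 300 * 4.184e-4 / atomic_masses(el),
                 tolerance = 0.05)
  }
})

test_that("with no forces, friction or heat the motion is uniform", {
  cfg <- configuration(c("C", "C"), rbind(c(2, 2, 2), c(8, 8, 8)),
                       cell(20, periodic = FALSE), wrap = FALSE)
  calc <- calculator(function(config)
    list(energy = 0, forces = matrix(0, 2, 3)),
    elements = "C", cutoff = 1, label = "null")
  v0 <- rbind(c(0.01, 0, 0), c(0, -0.02, 0))
  st <- md_state(cfg, v0)
  p <- md_params(dt = 0.5, friction = 0)
  for (k in 1:50) st <- langevin_step(st, calc, 0, p)$state
  expect_equal(st$config$positions,
               cfg$positions + 50 * 0.5 * v0, tolerance = 1e-12)
})

test_that("the zero-friction limit reproduces a standalone velocity-Verlet oracle", {
  calc <- harmonic_dimer_calc(k = 50, r0 = 1.2)
  cfg <- configuration(c("C", "C"), rbind(c(5, 5, 5), c(5, 5, 6.5)),
                       cell(20, periodic = FALSE), wrap = FALSE)
  v0 <- matrix(0, 2, 3)
  st <- md_state(cfg, v0)
  p <- md_params(dt = 0.5, friction = 0)
  for (k in 1:100) st <- langevin_step(st, calc, 0, p)$state
  xo <- verlet_oracle(cfg, v0, calc, 0.5, 100)
  expect_lt(max(abs(st$config$positions - xo)), 1e-10)
})

test_that("NVE energy is conserved on a harmonic dimer over 10,000 steps", {
  # soft mode (period ~ 190 fs) so the Verlet energy wobble is tiny
  kspr <- 0.5
  calc <- harmonic_dimer_calc(k = kspr, r0 = 1.2)
  cfg <- configuration(c("C", "C"), rbind(c(5, 5, 5), c(5, 5, 6.9)),
                       cell(20, periodic = FALSE), wrap = FALSE)
  st <- md_state(cfg)
  p <- md_params(dt = 0.5, friction = 0)
  m <- atomic_masses(cfg$species)
  etot <- numeric(10000)
  forces <- NULL
  for (k in 1:10000) {
    res <- langevin_step(st, calc, 0, p, forces = forces)
    st <- res$state; forces <- res$forces
    ke <- 0.5 * sum(m * rowSums(st$velocities^2)) / 4.184e-4
    etot[k] <- ke + res$energy
  }
  drift <- (max(etot) - min(etot)) / abs(etot[1])
  expect_lt(drift, 1e-4)
})

test_that("the Langevin thermostat recovers the target temperature", {
  set.seed(9)
  cfg <- pack_molecules(composition(CH4 = 4), density = 0.3)
  st <- md_state(cfg, maxwell_boltzmann_velocities(cfg$species, 300))
  p <- md_params(dt = 0.25, friction = 0.05, record_interval = 20)
  run <- run_md(st, toy_potential(), temp_constant(300), p, duration = 5000)
  temps <- run$trajectory$scalars$temperature
  t_mean <- mean(tail(temps, length(temps) %/% 2))
  expect_equal(t_mean, 300, tolerance = 0.05)
})

test_that("density rescaling is an exact similarity transform", {
  set.seed(10)
  cfg <- random_safe_box(16, 8)
  st <- md_state(cfg, matrix(0.01, 16, 3))
  rho0 <- mass_density(cfg)
  same <- rescale_to_density(st, rho0)
  expect_equal(same$config$positions, cfg$positions, tolerance = 1e-12)
  target <- rho0 * 1.7
  out <- rescale_to_density(st, target)
  expect_equal(mass_density(out$config), target, tolerance = 1e-9)
  frac0 <- sweep(cfg$positions, 2, cfg$cell$edge_lengths, "/")
  frac1 <- sweep(out$config$positions, 2, out$config$cell$edge_lengths, "/")
  expect_lt(max(abs(frac0 - frac1)), 1e-12)
  # minimum-image distances scale by (rho0/target)^(1/3)
  fac <- (rho0 / target)^(1 / 3)
  for (k in 1:10) {
    ij <- sample(16, 2)
    d0 <- minimum_image_displacement(cfg$positions[ij[1], ],
                                     cfg$positions[ij[2], ], cfg$cell)$distance
    d1 <- minimum_image_displacement(out$config$positions[ij[1], ],
                                     out$config$positions[ij[2], ],
                                     out$config$cell)$distance
    expect_equal(d1, d0 * fac, tolerance = 1e-9)
  }
})

test_that("run_md records the programmed frames and ramp targets", {
  ramp <- temp_ramp(300, 2500, 0, 100000)
  expect_equal(ramp(50000), 1400)
  pw <- temp_piecewise(c(0, 1000, 2000), c(100, 3000, 300))
  expect_equal(pw(500), 1550)
  set.seed(11)
  cfg <- pack_molecules(composition(H2 = 4), density = 0.1)
  st <- md_state(cfg, maxwell_boltzmann_velocities(cfg$species, 200))
  p <- md_params(dt = 0.5, friction = 0.02, record_interval = 100)
  run <- run_md(st, toy_potential(), temp_constant(200), p, duration = 500)
  expect_length(run$trajectory, 11L)   # initial frame + 10 recorded
  expect_equal(run$trajectory$times, seq(0, 500, by = 50))
  expect_named(run$trajectory$scalars,
               c("temperature", "density", "energy"))
})

test_that("center-of-mass drift under Langevin noise stays bounded", {
  set.seed(12)
  boxed <- build_random_carbon_box(64, 0.15)
  # open boundaries so center-of-mass motion is tracked without wrapping
  cfg <- configuration(boxed$species, boxed$positions,
                       cell(boxed$cell$edge_lengths, periodic = FALSE),
                       wrap = FALSE)
  m <- atomic_masses(cfg$species)
  com0 <- colSums(cfg$positions * m) / sum(m)
  st <- md_state(cfg, maxwell_boltzmann_velocities(cfg$species, 300))
  p <- md_params(dt = 0.5, friction = 0.05, record_interval = 2000)
  run <- run_md(st, toy_potential(), temp_constant(300), p, duration = 10000)
  com1 <- colSums(run$state$config$positions * m) / sum(m)
  expect_lt(sqrt(sum((com1 - com0)^2)), 1.0)
})
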