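# small, fast campaign configuration used across these tests
mini_al_config <- function(sims = 2L, t_max = 50, bootstrap = 16L,
                           target = 50) {
  al_config(
    bootstrap_cells = bootstrap, sims_per_generation = sims,
    t_max_fs = t_max, convergence_target_fs = target,
    builder = builder_policy(atom_range = c(8L, 12L),
                             density_range = c(0.25, 0.45),
                             molecules = c("CH4", "H2")),
    schedule_policy = schedule_policy(
      T_start = c(300, 800), T_end = c(500, 2000), T_amp = c(0, 400),
      rho_start = c(0.25, 0.6), rho_end = c(0.25, 0.6), rho_amp = c(0, 0.15),
      t_per = c(50, 200), t_max = t_max),
    md = md_params(dt = 0.5, friction = 0.01, record_interval = 1000L,
                   monitor_interval = 10L),
    train = train_config(lambda = 3e-3, energy_weight = 64),
    n_members = 8L,
    desc_params = test_desc_params(),
    relax_bootstrap = FALSE, relax_starts = FALSE)
}

test_that("the bootstrap dataset is built from seed molecules and labeled consistently", {
  set.seed(51)
  cfg <- mini_al_config(bootstrap = 10L)
  ds <- bootstrap_dataset(cfg, toy_potential())
  expect_s3_class(ds, "nr_dataset")
  expect_length(ds$samples, 10L)
  for (s in ds$samples) {
    expect_true(all(s$config$species %in% c("C", "H")))
  }
  # spot finite-difference check on one label
  s <- ds$samples[[3]]
  h <- 1e-5
  i <- sample(n_atoms(s$config), 1)
  cp <- s$config; cp$positions[i, 2] <- cp$positions[i, 2] + h
  cm <- s$config; cm$positions[i, 2] <- cm$positions[i, 2] - h
  fd <- -(toy_energy_forces(cp)$energy - toy_energy_forces(cm)$energy) / (2 * h)
  expect_equal(s$forces[i, 2], fd, tolerance = 1e-5 * max(1, abs(fd)))
})

test_that("a generation with unreachable thresholds leaves the dataset unchanged", {
  set.seed(53)
  cfg <- mini_al_config(sims = 2L, t_max = 25)
  cfg$thresholds <- selection_thresholds(1e9, 1e9)
  st <- al_state(bootstrap_dataset(cfg, toy_potential()), cfg)
  n0 <- length(st$dataset$samples)
  st <- al_generation(st, toy_potential())
  h <- st$history
  expect_equal(h$n_flagged, 0L)
  expect_equal(h$dataset_size, n0)
  expect_equal(h$mean_sim_time_fs, 25)
})

test_that("dataset growth equals the number of successfully labeled flags", {
  set.seed(55)
  cfg <- mini_al_config(sims = 3L, t_max = 50)
  st <- al_state(bootstrap_dataset(cfg, toy_potential()), cfg)
  n0 <- length(st$dataset$samples)
  st <- al_generation(st, toy_potential())
  h <- st$history
  expect_equal(h$dataset_size - n0, h$n_labeled)
  expect_lte(h$n_labeled, h$n_flagged)
  expect_equal(st$generation, 1L)
  # flagged times are multiples of the monitoring stride
  for (fr in st$flag_records[[1]]) {
    if (fr$reason == "threshold") {
      expect_equal(fr$time %% (10 * 0.5), 0)
    }
  }
})

test_that("campaigns are reproducible under a fixed seed", {
  run_once <- function() {
    set.seed(57)
    cfg <- mini_al_config(sims = 2L, t_max = 30)
    st <- al_state(bootstrap_dataset(cfg, toy_potential()), cfg)
    for (g in 1:2) st <- al_generation(st, toy_potential())
    st$history
  }
  h1 <- run_once()
  h2 <- run_once()
  expect_equal(h1, h2)
})

test_that("convergence control stops at the target or the generation cap", {
  set.seed(59)
  cfg <- mini_al_config(sims = 1L, t_max = 25, target = 1e-9)
  st <- al_state(bootstrap_dataset(cfg, toy_potential()), cfg)
  out <- run_until_converged(st, toy_potential(), max_generations = 5L)
  expect_equal(out$generation, 1L)     # any mean time satisfies a ~zero target
  expect_true(attr(out, "converged"))

  set.seed(61)
  cfg2 <- mini_al_config(sims = 1L, t_max = 25, target = 1e9)
  st2 <- al_state(bootstrap_dataset(cfg2, toy_potential()), cfg2)
  out2 <- run_until_converged(st2, toy_potential(), max_generations = 1L)
  expect_equal(out2$generation, 1L)
  expect_false(attr(out2, "converged"))
})

test_that("generation thresholds ramp from half to full strength", {
  final <- selection_thresholds()
  t1 <- generation_thresholds(1, final, ramp = 5)
  t5 <- generation_thresholds(5, final, ramp = 5)
  t9 <- generation_thresholds(9, final, ramp = 5)
  expect_equal(t1$energy, 0.5 * 1.85)
  expect_equal(t5$energy, 1.85)
  expect_equal(t9$force, 6.92)
})

test_that("tidiers summarize campaign state", {
  set.seed(63)
  cfg <- mini_al_config(sims = 1L, t_max = 25)
  st <- al_state(bootstrap_dataset(cfg, toy_potential()), cfg)
  st <- al_generation(st, toy_potential())
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  gl <- glance(st)
  expect_equal(gl$generations, 1L)
  te <- tidy(st$ensemble)
  expect_equal(nrow(te), 8L)
  expect_true(all(c("rmse_energy_test", "rmse_force_val") %in% names(te)))
})
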