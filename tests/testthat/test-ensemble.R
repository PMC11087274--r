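# a minimal stand-in ensemble object for hand-computed QBC cases
fake_prediction <- function(energies, forces) {
  list(energies = energies, forces = forces,
       mean_energy = mean(energies),
       mean_forces = Reduce(`+`, forces) / length(forces))
}

test_that("query-by-committee uncertainty matches hand computations", {
  cfg <- configuration(rep("H", 4), matrix(runif(12, 0, 5), 4, 3), cell(5))
  shell <- structure(list(n_members = 2L), class = "nr_ensemble")
  f0 <- matrix(0, 4, 3)
  # identical members -> (0, 0)
  eps <- qbc_uncertainty(shell, cfg,
                         prediction = fake_prediction(c(1, 1), list(f0, f0)))
  expect_equal(eps$energy, 0)
  expect_equal(eps$force, 0)
  # member energies {0, 2} at N = 4 -> population std 1 / sqrt(4) = 0.5
  eps <- qbc_uncertainty(shell, cfg,
                         prediction = fake_prediction(c(0, 2), list(f0, f0)))
  expect_equal(eps$energy, 0.5)
  expect_equal(eps$force, 0)
  # forces differing by (2d, 0, 0) on one atom -> eps_F = d
  d <- 0.37
  f1 <- f0; f1[3, 1] <- 2 * d
  eps <- qbc_uncertainty(shell, cfg,
                         prediction = fake_prediction(c(1, 1), list(f0, f1)))
  expect_equal(eps$force, d, tolerance = 1e-12)
  # mean aggregation: d/4 over the four atoms
  eps_m <- qbc_uncertainty(shell, cfg, aggregate = "mean",
                           prediction = fake_prediction(c(1, 1), list(f0, f1)))
  expect_equal(eps_m$force, d / 4, tolerance = 1e-12)
})

test_that("the energy uncertainty scales as 1/sqrt(N) at fixed member spread", {
  shell <- structure(list(n_members = 2L), class = "nr_ensemble")
  for (N in c(4, 16, 64)) {
    cfg <- configuration(rep("H", N), matrix(runif(3 * N, 0, 20), N, 3),
                         cell(20))
    f0 <- matrix(0, N, 3)
    eps <- qbc_uncertainty(shell, cfg,
                           prediction = fake_prediction(c(0, 2), list(f0, f0)))
    expect_equal(eps$energy, 1 / sqrt(N), tolerance = 1e-12)
  }
})

test_that("threshold exceedance uses strict inequality against the final values", {
  thr <- selection_thresholds()
  expect_equal(thr$energy, 1.85)
  expect_equal(thr$force, 6.92)
  expect_false(exceeds_thresholds(list(energy = 0, force = 0), thr))
  expect_true(exceeds_thresholds(list(energy = 1.86, force = 0), thr))
  expect_true(exceeds_thresholds(list(energy = 0, force = 6.93), thr))
  expect_false(exceeds_thresholds(list(energy = 1.85, force = 6.92), thr))
})

test_that("training recovers the toy surface on a dimer distance sweep", {
  mk_dimer <- function(r) configuration(c("C", "H"),
                                        rbind(c(10, 10, 10), c(10, 10, 10 + r)),
                                        cell(20, periodic = FALSE), wrap = FALSE)
  set.seed(31)
  rs <- seq(0.8, 2.0, length.out = 200)
  samples <- label_configurations(lapply(rs, mk_dimer), toy_potential())$samples
  ens <- train_ensemble(samples, test_desc_params(), train_config(), 8)
  rmse <- vapply(ens$metrics, function(m) m$test$rmse_energy_per_atom,
                 numeric(1))
  expect_true(all(rmse < 0.5))

  # member forces are exact negative gradients (finite differences)
  cfg <- mk_dimer(1.37)
  mb <- ens$members[[5]]
  pr <- predict_member(mb, cfg)
  h <- 1e-5
  for (d in 1:3) {
    cp <- cfg; cp$positions[2, d] <- cp$positions[2, d] + h
    cm <- cfg; cm$positions[2, d] <- cm$positions[2, d] - h
    fd <- -(predict_member(mb, cp)$energy - predict_member(mb, cm)$energy) / (2 * h)
    expect_equal(pr$forces[2, d], fd, tolerance = 1e-5 * max(0.1, abs(fd)))
  }

  # rigid translation leaves the member energy unchanged
  shifted <- cfg
  shifted$positions <- sweep(shifted$positions, 2, c(2.1, -1.2, 0.4), "+")
  expect_equal(predict_member(mb, shifted)$energy, pr$energy,
               tolerance = 1e-8)

  # committee disagreement far outside the trained distance range exceeds
  # the disagreement at training geometries (extrapolation detection)
  eps_train <- median(vapply(seq(1.0, 1.9, length.out = 10), function(r)
    qbc_uncertainty(ens, mk_dimer(r))$force, numeric(1)))
  eps_far <- median(vapply(seq(2.6, 3.1, length.out = 10), function(r)
    qbc_uncertainty(ens, mk_dimer(r))$force, numeric(1)))
  expect_gt(eps_far, eps_train)
})

test_that("isolated atoms give additive per-element baseline energies", {
  set.seed(33)
  samples <- toy_box_dataset(8)
  ens <- train_ensemble(samples, test_desc_params(), train_config(), 8)
  mb <- ens$members[[1]]
  far <- configuration(c("C", "H"), rbind(c(5, 5, 5), c(45, 45, 45)),
                       cell(90, periodic = FALSE), wrap = FALSE)
  eC <- predict_member(mb, configuration("C", matrix(c(1, 1, 1), 1),
                                         cell(90, periodic = FALSE), wrap = FALSE))$energy
  eH <- predict_member(mb, configuration("H", matrix(c(1, 1, 1), 1),
                                         cell(90, periodic = FALSE), wrap = FALSE))$energy
  expect_equal(predict_member(mb, far)$energy, eC + eH, tolerance = 1e-8)
})

test_that("training is reproducible and validates the block split", {
  set.seed(35)
  samples <- toy_box_dataset(6)   # 18 samples
  dp <- test_desc_params()
  set.seed(41); e1 <- train_ensemble(samples, dp, train_config(), 8)
  set.seed(41); e2 <- train_ensemble(samples, dp, train_config(), 8)
  expect_equal(e1$members[[3]]$theta, e2$members[[3]]$theta, tolerance = 1e-10)
  expect_equal(vapply(e1$metrics, function(m) m$test$rmse_force, numeric(1)),
               vapply(e2$metrics, function(m) m$test$rmse_force, numeric(1)),
               tolerance = 1e-10)
  expect_error(train_ensemble(samples[1:10], dp, train_config(), 8),
               "16-block")
  expect_error(train_ensemble(samples, dp, train_config(), 1), "n_members")
})
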