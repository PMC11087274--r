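test_that("minimum-image displacement handles identity, wrapping and open boundaries", {
  cl <- cell(10)
  expect_equal(minimum_image_displacement(c(1, 2, 3), c(1, 2, 3), cl)$distance, 0)
  expect_equal(minimum_image_displacement(c(9, 0, 0), c(1, 0, 0), cl)$distance, 2)
  open_cl <- cell(10, periodic = FALSE)
  expect_equal(minimum_image_displacement(c(9, 0, 0), c(1, 0, 0), open_cl)$distance, 8)
  expect_error(minimum_image_displacement(c(NA, 0, 0), c(0, 0, 0), cl), "finite")
})

test_that("wrapping positions changes no minimum-image distance", {
  set.seed(1)
  cfg <- configuration(rep("C", 20), matrix(runif(60, -15, 25), 20, 3),
                       cell(c(8, 10, 12)), wrap = FALSE)
  wrapped <- wrap_config(cfg)
  frac <- sweep(wrapped$positions, 2, wrapped$cell$edge_lengths, "/")
  expect_true(all(frac >= 0 & frac < 1))
  for (k in 1:25) {
    i <- sample(20, 1); j <- sample(20, 1)
    d1 <- minimum_image_displacement(cfg$positions[i, ], cfg$positions[j, ], cfg$cell)$distance
    d2 <- minimum_image_displacement(wrapped$positions[i, ], wrapped$positions[j, ], cfg$cell)$distance
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("mass density reproduces the case-study box arithmetic", {
  set.seed(3)
  methane <- pack_molecules(composition_preset("methane_combustion"),
                            cell = cell(37.60))
  expect_equal(n_atoms(methane), 900L)
  expect_equal(mass_density(methane), 0.25, tolerance = 0.005)

  miller <- pack_molecules(composition_preset("miller"), cell = cell(12.1))
  expect_equal(n_atoms(miller), 228L)
  expect_equal(mass_density(miller), 1.067, tolerance = 0.005)

  expect_equal(composition_atoms(composition_preset("acetylene")), 1000L)
})

test_that("mass density obeys scaling, translation and reordering identities", {
  set.seed(4)
  cfg <- configuration(sample(c("C", "H", "O"), 12, TRUE),
                       matrix(runif(36, 0, 6), 12, 3), cell(6))
  rho <- mass_density(cfg)
  big <- configuration(cfg$species, cfg$positions, cell(12))
  expect_equal(mass_density(big), rho / 8, tolerance = 1e-12)
  shifted <- cfg; shifted$positions <- shifted$positions + 3.21
  expect_equal(mass_density(wrap_config(shifted)), rho)
  ord <- sample(12)
  reord <- configuration(cfg$species[ord], cfg$positions[ord, ], cfg$cell)
  expect_equal(mass_density(reord), rho)
  expect_error(mass_density(configuration(character(0),
                                          matrix(numeric(0), 0, 3), cell(5))),
               "no atoms")
})

test_that("neighbor lists match the brute-force minimum-image oracle", {
  set.seed(7)
  cfg <- configuration(sample(c("C", "H"), 100, TRUE),
                       matrix(runif(300, 0, 12), 100, 3), cell(12))
  got <- neighbor_pairs(cfg, 3.0)
  ref <- brute_pairs(cfg, 3.0)
  expect_equal(got$i, ref$i)
  expect_equal(got$j, ref$j)
  expect_equal(got$dist, ref$dist, tolerance = 1e-10)
  expect_equal(nrow(neighbor_pairs(cfg, 0)), 0L)
})

test_that("cell-linked list and brute force agree exactly", {
  set.seed(8)
  cfg <- configuration(rep("C", 260), matrix(runif(780, 0, 16), 260, 3),
                       cell(16))
  a <- neighbor_pairs(cfg, 2.4, method = "brute")
  b <- neighbor_pairs(cfg, 2.4, method = "cell")
  expect_equal(a, b)
})

test_that("every diamond-lattice atom has exactly four first-shell neighbors", {
  a <- 3.567
  cfg <- diamond_lattice(a, replicas = 2)
  cutoff <- (a * sqrt(3) / 4 + a / sqrt(2)) / 2   # between shells
  np <- neighbor_pairs(cfg, cutoff)
  deg <- tabulate(c(np$i, np$j), nbins = n_atoms(cfg))
  expect_true(all(deg == 4L))
  expect_equal(min(np$dist), a * sqrt(3) / 4, tolerance = 1e-12)
})

test_that("over-long cutoffs error unless multi-image handling is requested", {
  cfg <- configuration(c("C", "C"), rbind(c(1, 1, 1), c(3, 3, 3)), cell(6))
  expect_error(neighbor_pairs(cfg, 4.0), "multi_image")
  np <- neighbor_pairs(cfg, 4.0, multi_image = TRUE)
  ref <- brute_pairs(cfg, 4.0, shells = 2L)
  expect_equal(np$dist, ref$dist, tolerance = 1e-10)
})

test_that("trajectory and labeled-sample containers validate their invariants", {
  cfg <- configuration(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), cell(5))
  expect_error(trajectory(list(cfg, cfg), c(0, 0)), "strictly increasing")
  cfg2 <- configuration(c("H", "O"), cfg$positions, cfg$cell)
  expect_error(trajectory(list(cfg, cfg2), c(0, 1)), "species")
  expect_error(labeled_sample(cfg, 1.0, matrix(0, 3, 3)), "N x 3")
  expect_error(labeled_sample(cfg, NaN, matrix(0, 2, 3)), "finite")
})
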