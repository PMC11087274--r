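test_that("the seed library holds exactly the nine molecules with sane geometry", {
  expect_length(seed_molecule_names(), 9L)
  expect_setequal(seed_molecule_names(),
                  c("C2", "H2", "N2", "O2", "NH3", "CH4", "CO2", "H2O", "C2H2"))
  ch4 <- seed_molecule("CH4")
  expect_equal(sort(ch4$species), c("C", "H", "H", "H", "H"))
  expect_error(seed_molecule("XYZ"), "valid names")
  # CO only through the extended table (Miller experiment)
  expect_error(seed_molecule("CO"))
  expect_silent(seed_molecule("CO", extended = TRUE))
  # every seed: all bonded (nearest-neighbor) distances within 0.7-1.8 A,
  # and at most two non-hydrogen atoms
  for (nm in seed_molecule_names()) {
    mol <- seed_molecule(nm)
    expect_lte(sum(mol$species != "H"), if (nm == "CO2") 3L else 2L)
    n <- nrow(mol$positions)
    if (n < 2L) next
    d <- as.matrix(dist(mol$positions))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    expect_true(all(nn > 0.7 & nn < 1.8), info = nm)
  }
})

test_that("carbon rejection sampling honors twice the 1.7 A van der Waals radius", {
  set.seed(11)
  cfg <- build_random_carbon_box(200, 0.5)
  expect_equal(n_atoms(cfg), 200L)
  expect_equal(mass_density(cfg), 0.5, tolerance = 1e-3)
  viol <- brute_pairs(cfg, 2 * 1.7)
  expect_equal(nrow(viol), 0L)
  single <- build_random_carbon_box(1, 2.0)
  expect_equal(n_atoms(single), 1L)
})

test_that("infeasible carbon densities are rejected with a packing bound", {
  expect_error(build_random_carbon_box(200, 2.25), "packing fraction")
})

test_that("the molecule packer separates molecules by the requested distance", {
  set.seed(13)
  comp <- composition(CH4 = 20, O2 = 40)
  cfg <- pack_molecules(comp, density = 0.25)
  expect_equal(n_atoms(cfg), 20L * 5L + 40L * 2L)
  expect_equal(mass_density(cfg), 0.25, tolerance = 1e-3)
  mid <- attr(cfg, "molecule_id")
  np <- brute_pairs(cfg, 2.0)
  inter <- np[mid[np$i] != mid[np$j], ]
  expect_equal(nrow(inter), 0L)
})

test_that("a single packed molecule preserves the template geometry rigidly", {
  set.seed(17)
  cfg <- pack_molecules(composition(NH3 = 1), cell = cell(12))
  tpl <- seed_molecule("NH3")
  d_tpl <- as.matrix(dist(tpl$positions))
  n <- n_atoms(cfg)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- minimum_image_displacement(cfg$positions[i, ], cfg$positions[j, ],
                                    cfg$cell)$distance
    expect_equal(d, d_tpl[i, j], tolerance = 1e-9)
  }
})

test_that("random systems respect the policy's atom and element constraints", {
  pol <- builder_policy(atom_range = c(10L, 24L), density_range = c(0.2, 0.5))
  set.seed(19)
  for (k in 1:12) {
    cfg <- random_nr_system(pol)
    expect_gte(n_atoms(cfg), 10L)
    expect_lte(n_atoms(cfg), 24L)
    expect_true(all(cfg$species %in% c("H", "C", "N", "O")))
    rho <- mass_density(cfg)
    expect_gte(rho, 0.2 - 1e-9)
    expect_lte(rho, 0.5 + 1e-9)
  }
})

test_that("builders are reproducible under a fixed seed", {
  pol <- builder_policy(atom_range = c(10L, 20L), density_range = c(0.2, 0.5),
                        molecules = c("CH4", "H2O"))
  set.seed(23); a <- random_nr_system(pol)
  set.seed(23); b <- random_nr_system(pol)
  expect_identical(a$species, b$species)
  expect_equal(a$positions, b$positions)
  set.seed(29); c1 <- build_random_carbon_box(60, 0.4)
  set.seed(29); c2 <- build_random_carbon_box(60, 0.4)
  expect_equal(c1$positions, c2$positions)
})

test_that("a degenerate policy yields a deterministic composition", {
  pol <- builder_policy(atom_range = c(9L, 9L), density_range = c(0.3, 0.3),
                        molecules = "H2O")
  set.seed(31)
  cfg <- random_nr_system(pol)
  comp <- attr(cfg, "composition")
  expect_equal(unname(comp[["H2O"]]), 3L)
  expect_true(all(cfg$species %in% c("H", "O")))
  expect_equal(mass_density(cfg), 0.3, tolerance = 1e-9)
})
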