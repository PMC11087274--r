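test_that("bond rules reproduce the printed carbon-carbon cutoff", {
  rules <- bond_rules()
  expect_equal(bond_cutoff(rules, "C", "C"), 1.72)
  two_c <- function(r) configuration(c("C", "C"),
                                     rbind(c(5, 5, 5), c(5, 5, 5 + r)),
                                     cell(20))
  g171 <- detect_bonds(two_c(1.71), rules)
  g173 <- detect_bonds(two_c(1.73), rules)
  expect_equal(igraph::ecount(g171), 1)
  expect_equal(igraph::ecount(g173), 0)
  single <- detect_bonds(configuration("C", matrix(c(1, 1, 1), 1), cell(10)))
  expect_equal(igraph::ecount(single), 0)
  expect_error(detect_bonds(configuration("F", matrix(c(1, 1, 1), 1), cell(10)),
                            rules), "radius")
})

test_that("the diamond fixture has uniform degree four", {
  g <- detect_bonds(diamond_lattice(3.567, 2))
  expect_true(all(igraph::degree(g) == 4L))
})

test_that("molecule extraction matches a union-find oracle", {
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "element", value = rep("C", 5))
  expect_length(extract_molecules(g0), 5L)
  set.seed(21)
  for (k in 1:15) {
    n <- sample(5:50, 1)
    gl <- random_labeled_graph(n, p = 2 / n)
    mols <- extract_molecules(gl$graph)
    edges <- igraph::as_edgelist(gl$graph, names = FALSE)
    ref <- uf_components(n, edges)
    norm <- function(x) unname(lapply(x[order(vapply(x, min, numeric(1)))], sort))
    expect_equal(norm(mols), norm(ref))
  }
})

test_that("a packed Miller box splits into 72 molecules of 5 species", {
  set.seed(23)
  cfg <- pack_molecules(composition_preset("miller"), cell = cell(12.1))
  g <- detect_bonds(cfg)
  mols <- extract_molecules(g)
  expect_length(mols, 72L)
  census <- count_unique_species(cfg)
  expect_equal(nrow(census$species), 5L)
  expect_setequal(census$species$formula, c("H2", "H2O", "CO", "H3N", "CH4"))
})

test_that("canonical keys agree with brute-force isomorphism", {
  # relabeling invariance
  set.seed(25)
  gl <- random_labeled_graph(8, p = 0.35)
  perm <- sample(8)
  gp <- igraph::permute(gl$graph, perm)
  expect_identical(canonical_key(gl$graph), canonical_key(gp))
  # ethanol-like vs dimethyl-ether-like C2H6O topologies
  mk_graph <- function(el, edges) {
    g <- igraph::make_empty_graph(length(el), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "element", value = el)
    igraph::add_edges(g, t(edges))
  }
  el <- c("C", "C", "O", rep("H", 6))
  ethanol <- mk_graph(el, rbind(c(1, 2), c(2, 3), c(3, 4),
                                c(1, 5), c(1, 6), c(1, 7), c(2, 8), c(2, 9)))
  ether <- mk_graph(el, rbind(c(1, 3), c(2, 3),
                              c(1, 4), c(1, 5), c(1, 6),
                              c(2, 7), c(2, 8), c(2, 9)))
  expect_false(canonical_key(ethanol) == canonical_key(ether))
  # random sweep: key equality == brute-force isomorphism
  set.seed(27)
  graphs <- replicate(40, random_labeled_graph(sample(3:8, 1), p = 0.5),
                      simplify = FALSE)
  keys <- vapply(graphs, function(g) canonical_key(g$graph), character(1))
  for (a in 1:39) for (b in (a + 1):40) {
    iso <- brute_isomorphic(graphs[[a]]$adj, graphs[[a]]$lab,
                            graphs[[b]]$adj, graphs[[b]]$lab)
    expect_identical(keys[a] == keys[b], iso,
                     label = paste("pair", a, b))
  }
})

test_that("ring censuses count minimum-cycle-basis rings by size", {
  # acyclic
  chain <- hexagonal_sheet(1)
  g_acyclic <- detect_bonds(configuration(c("C", "C", "C"),
                                          rbind(c(1, 1, 1), c(2.4, 1, 1), c(3.8, 1, 1)),
                                          cell(10, periodic = FALSE), wrap = FALSE))
  expect_true(all(ring_census(g_acyclic) == 0L))
  # one hexagon
  expect_equal(unname(ring_census(detect_bonds(hexagonal_sheet(1)))["6"]), 1L)
  # fused strip of k hexagons
  for (k in c(2, 3, 5)) {
    rc <- ring_census(detect_bonds(hexagonal_sheet(k)))
    expect_equal(unname(rc["6"]), k)
    expect_equal(sum(rc), k)
  }
  # carbon-only filter leaves the pure-carbon census unchanged
  rc_c <- ring_census(detect_bonds(hexagonal_sheet(3)), elements = "C")
  expect_equal(unname(rc_c["6"]), 3L)
})

test_that("species tracking follows a scripted reaction and conserves atoms", {
  tr <- reaction_toy_trajectory("2H2+O2->2H2O@3", n_frames = 5)
  series <- track_species(tr, targets = c("H2", "O2", "H2O"))
  h2 <- series$count[series$target == "H2"]
  h2o <- series$count[series$target == "H2O"]
  expect_equal(h2, c(2L, 2L, 0L, 0L, 0L))
  expect_equal(h2o, c(0L, 0L, 2L, 2L, 2L))
  # census totals partition the atom count in every frame
  census <- count_unique_species(tr)
  atoms_per <- c(H2 = 2L, O2 = 2L, H2O = 3L)
  totals <- census$counts |>
    dplyr::mutate(atoms = .data$count * atoms_per[.data$formula]) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(n = sum(.data$atoms))
  expect_true(all(totals$n == n_atoms(tr$frames[[1]])))
  expect_error(track_species(tr, targets = "notAFormula!"), "target")
})

test_that("ignition delay time averages the three first crossings", {
  mk_series <- function(times, co, co2, h2o) {
    tibble::tibble(frame = rep(seq_along(times), 3),
                   time = rep(times, 3),
                   target = rep(c("CO", "CO2", "H2O"), each = length(times)),
                   count = c(co, co2, h2o))
  }
  t <- seq(0, 40000, by = 10000)
  s <- mk_series(t, co = c(0, 5, 6, 7, 8), co2 = c(0, 0, 5, 6, 7),
                 h2o = c(0, 0, 0, 5, 6))
  expect_equal(ignition_delay_time(s), mean(c(10000, 20000, 30000)))
  s0 <- mk_series(t, co = rep(9, 5), co2 = rep(7, 5), h2o = rep(5, 5))
  expect_equal(ignition_delay_time(s0), 0)
  s_never <- mk_series(t, co = c(0, 5, 6, 7, 8), co2 = c(0, 0, 5, 6, 7),
                       h2o = c(0, 1, 2, 3, 4))
  expect_true(is.na(ignition_delay_time(s_never)))
  s_bad <- s
  s_bad$time[s_bad$target == "CO"] <- s_bad$time[s_bad$target == "CO"] + 1
  expect_error(ignition_delay_time(s_bad), "grids")
})
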