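# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry/graph machinery.

# O(N^2) minimum-image pair scan with explicit image enumeration.
brute_pairs <- function(config, cutoff, shells = 1L) {
  pos <- config$positions
  L <- config$cell$edge_lengths
  per <- config$cell$periodic
  N <- nrow(pos)
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  sh <- -shells:shells
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    best <- Inf
    for (sx in (if (per[1]) sh else 0L))
      for (sy in (if (per[2]) sh else 0L))
        for (sz in (if (per[3]) sh else 0L)) {
          d <- pos[j, ] + c(sx * L[1], sy * L[2], sz * L[3]) - pos[i, ]
          best <- min(best, sqrt(sum(d^2)))
        }
    if (best < cutoff) {
      res_i <- c(res_i, i); res_j <- c(res_j, j); res_d <- c(res_d, best)
    }
  }
  data.frame(i = res_i, j = res_j, dist = res_d)
}

# union-find connected components; edges is a 2-column matrix
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x, parent) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1], parent); rb <- find(edges[k, 2], parent)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1), parent = parent)
  split(seq_len(n), match(roots, unique(roots)))
}

# brute-force element-labeled graph isomorphism by backtracking over
# degree/label-compatible assignments
brute_isomorphic <- function(adj1, lab1, adj2, lab2) {
  n <- nrow(adj1)
  if (n != nrow(adj2)) return(FALSE)
  if (!identical(sort(lab1), sort(lab2))) return(FALSE)
  deg1 <- rowSums(adj1); deg2 <- rowSums(adj2)
  if (!identical(sort(deg1), sort(deg2))) return(FALSE)
  used <- rep(FALSE, n)
  map <- rep(NA_integer_, n)
  try_assign <- function(v) {
    if (v > n) return(TRUE)
    for (w in seq_len(n)) {
      if (used[w] || lab1[v] != lab2[w] || deg1[v] != deg2[w]) next
      ok <- TRUE
      for (u in seq_len(v - 1L)) {
        if (adj1[v, u] != adj2[w, map[u]]) { ok <- FALSE; break }
      }
      if (!ok) next
      used[w] <<- TRUE; map[v] <<- w
      if (try_assign(v + 1L)) return(TRUE)
      used[w] <<- FALSE; map[v] <<- NA_integer_
    }
    FALSE
  }
  try_assign(1L)
}

# random element-labeled connected graph as igraph with `element` attr
random_labeled_graph <- function(n, p = 0.4, elements = c("C", "H")) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < p) { adj[i, j] <- 1L; adj[j, i] <- 1L }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g) || n == 1L) {
      lab <- sample(elements, n, replace = TRUE)
      g <- igraph::set_vertex_attr(g, "element", value = lab)
      return(list(graph = g, adj = adj, lab = lab))
    }
  }
}

# harmonic dimer calculator: V = 0.5 k (r - r0)^2, non-periodic
harmonic_dimer_calc <- function(k, r0) {
  calculator(function(config) {
    d <- config$positions[2, ] - config$positions[1, ]
    r <- sqrt(sum(d^2))
    u <- d / r
    f <- -k * (r - r0)
    forces <- rbind(-f * u, f * u)
    list(energy = 0.5 * k * (r - r0)^2, forces = forces)
  }, elements = c("H", "C", "N", "O"), cutoff = Inf, label = "harmonic")
}

# standalone velocity-Verlet oracle (positions only)
verlet_oracle <- function(config, velocities, calc, dt, n_steps) {
  m <- atomic_masses(config$species)
  x <- config$positions
  v <- velocities
  conv <- 4.184e-4
  f <- calc$evaluate(config)$forces
  for (k in seq_len(n_steps)) {
    a <- f * conv / m
    vh <- v + 0.5 * dt * a
    x <- x + 0.5 * dt * vh          # two half drifts, matching BAOAB
    x <- x + 0.5 * dt * vh
    cfg <- config; cfg$positions <- x
    cfg <- wrap_config(cfg)
    x <- cfg$positions
    f <- calc$evaluate(cfg)$forces
    v <- vh + 0.5 * dt * (f * conv / m)
  }
  x
}

# a random box with no pair closer than min_r (for force checks)
random_safe_box <- function(n, L, elements = c("C", "H", "N", "O"),
                            min_r = 0.95) {
  repeat {
    cfg <- configuration(sample(elements, n, replace = TRUE),
                         matrix(stats::runif(3 * n, 0, L), n, 3), cell(L))
    if (nrow(neighbor_pairs(cfg, min_r, multi_image = TRUE)) == 0L)
      return(cfg)
  }
}

# small labeled dataset from the toy potential for ensemble tests:
# packed CH4/H2 boxes plus mildly perturbed copies
toy_box_dataset <- function(n_boxes, pol = NULL, pert = c(0.03, 0.07)) {
  if (is.null(pol)) {
    pol <- builder_policy(atom_range = c(8L, 14L),
                          density_range = c(0.25, 0.45),
                          molecules = c("CH4", "H2"))
  }
  configs <- list()
  for (k in seq_len(n_boxes)) {
    sys <- random_nr_system(pol)
    configs[[length(configs) + 1L]] <- sys
    for (sdp in pert) {
      p <- sys
      p$positions <- p$positions +
        matrix(stats::rnorm(3 * n_atoms(sys), sd = sdp), ncol = 3)
      configs[[length(configs) + 1L]] <- p
    }
  }
  label_configurations(configs, toy_potential())$samples
}

# descriptor parameters matched to the toy potential's range, used by the
# ensemble and campaign tests (kept small for speed)
test_desc_params <- function(elements = c("C", "H")) {
  descriptor_params(elements = elements,
                    radial_centers = seq(0.55, 3.1, length.out = 16),
                    radial_eta = 24, angular_sections = 2,
                    angular_centers = 1.5)
}
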