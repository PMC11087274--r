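#' Seed molecule library
#'
#' The nine small molecules used to initialize nanoreactor sampling:
#' C2, H2, N2, O2, NH3, CH4, CO2, H2O and C2H2. Geometries are idealized
#' equilibrium structures (standard bond lengths and angles); every seed
#' has at most two non-hydrogen atoms.
#'
#' @format A molecule is a list with `name`, `species` and `positions`
#'   (n x 3 Cartesian template, Angstrom, centered on the centroid).
#' @name seed-molecules
NULL

# Internal geometry table. CO is included for the Miller-experiment builder
# but is not part of the nine-molecule seed library.
.molecule_geometries <- local({
  geom <- function(species, positions) {
    if (!is.matrix(positions))
      positions <- matrix(positions, ncol = 3, byrow = TRUE)
    positions <- sweep(positions, 2, colMeans(positions), "-")
    list(species = species, positions = positions)
  }
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  ang_h2o <- 104.5 * pi / 180
  # NH3: pyramidal, HNH 106.7 deg -> place H on a cone about z
  hnh <- 106.7 * pi / 180
  # relation between cone half-angle theta (from axis) and HNH angle:
  # cos(HNH) = cos^2(theta) + sin^2(theta) * cos(120 deg)
  ct2 <- (cos(hnh) + 0.5) / 1.5
  theta <- acos(sqrt(ct2))
  rNH <- 1.012
  nh3_h <- t(vapply(0:2, function(k) {
    phi <- 2 * pi * k / 3
    rNH * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }, numeric(3)))
  list(
    H2  = geom(c("H", "H"), c(0, 0, 0, 0, 0, 0.741)),
    N2  = geom(c("N", "N"), c(0, 0, 0, 0, 0, 1.098)),
    O2  = geom(c("O", "O"), c(0, 0, 0, 0, 0, 1.208)),
    C2  = geom(c("C", "C"), c(0, 0, 0, 0, 0, 1.243)),
    CO  = geom(c("C", "O"), c(0, 0, 0, 0, 0, 1.128)),
    CO2 = geom(c("O", "C", "O"), c(0, 0, -1.162, 0, 0, 0, 0, 0, 1.162)),
    H2O = geom(c("O", "H", "H"),
               rbind(c(0, 0, 0),
                     0.958 * c(sin(ang_h2o / 2), 0, cos(ang_h2o / 2)),
                     0.958 * c(-sin(ang_h2o / 2), 0, cos(ang_h2o / 2)))),
    NH3 = geom(c("N", "H", "H", "H"), rbind(c(0, 0, 0), nh3_h)),
    CH4 = geom(c("C", "H", "H", "H", "H"),
               rbind(c(0, 0, 0), 1.087 * tetra)),
    C2H2 = geom(c("H", "C", "C", "H"),
                c(0, 0, -1.6645, 0, 0, -0.6015, 0, 0, 0.6015, 0, 0, 1.6645))
  )
})

#' Names of the nine seed molecules
#' @return character vector of length 9.
#' @export
seed_molecule_names <- function() {
  setdiff(names(.molecule_geometries), "CO")
}

#' Retrieve a seed molecule template
#'
#' @param name one of the nine seed molecule names (see
#'   [seed_molecule_names()]); `extended = TRUE` additionally allows CO,
#'   needed for the Miller-experiment composition.
#' @param extended allow molecules beyond the nine-seed library.
#' @return list with `name`, `species`, `positions`.
#' @export
seed_molecule <- function(name, extended = FALSE) {
  valid <- if (extended) names(.molecule_geometries) else seed_molecule_names()
  if (!name %in% valid) {
    stop("unknown molecule '", name, "'; valid names: ",
         paste(sort(valid), collapse = ", "))
  }
  g <- .molecule_geometries[[name]]
  list(name = name, species = g$species, positions = g$positions)
}

#' Molecular composition
#'
#' @param ... named counts, e.g. `composition(CH4 = 100, O2 = 200)`, or a
#'   single named numeric vector/list.
#' @return named integer vector of class `nr_composition`.
#' @export
composition <- function(...) {
  x <- c(...)
  if (is.list(x)) x <- unlist(x)
  counts <- as.integer(x)
  names(counts) <- names(x)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("composition entries must be named by molecule")
  if (any(counts < 0)) stop("composition counts must be >= 0")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("composition must contain at least one molecule")
  structure(counts, class = "nr_composition")
}

#' Total atom count of a composition
#' @param comp an [composition()].
#' @param extended passed to [seed_molecule()].
#' @return integer.
#' @export
composition_atoms <- function(comp, extended = TRUE) {
  sum(vapply(names(comp), function(nm)
    length(seed_molecule(nm, extended = extended)$species), integer(1)) *
      as.integer(comp))
}

# Cubic box edge so that a given species list has the requested density.
box_edge_for_density <- function(species, density) {
  mass_g <- sum(atomic_masses(species)) * NR_AMU_G
  (mass_g / density * 1e24)^(1 / 3)
}

#' Random carbon box by sequential rejection sampling
#'
#' Builds an amorphous all-carbon start: a cubic cell sized for the
#' requested density, atoms inserted sequentially at uniform random
#' positions and accepted only when at least `min_distance` (default twice
#' the 1.7 A carbon van der Waals radius) from all previously placed atoms
#' under the minimum-image convention.
#'
#' Dense requests can exceed the saturation limit of pure sequential
#' rejection (packing fraction ~0.38) while remaining geometrically
#' feasible; in that regime the builder falls back to a force-biased
#' relaxation (random start, exclusion diameter grown gradually while
#' overlapping pairs are pushed apart) that honours the same distance
#' guarantee. Requests beyond random close packing (fraction 0.64) error.
#'
#' @param n_atoms number of carbon atoms.
#' @param density target mass density (g/cc).
#' @param min_distance minimum pairwise minimum-image distance (Angstrom).
#' @param max_attempts rejection-sampling proposals per atom before the
#'   relaxation fallback engages.
#' @return an [configuration()] of `n_atoms` C atoms. The realized density
#'   matches the request to well under 0.1%.
#' @export
build_random_carbon_box <- function(n_atoms, density,
                                    min_distance = 2 * 1.7,
                                    max_attempts = 10000L) {
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  species <- rep("C", n_atoms)
  L <- box_edge_for_density(species, density)
  V <- L^3
  phi <- if (n_atoms > 1L)
    n_atoms * (4 / 3) * pi * (min_distance / 2)^3 / V else 0
  if (phi > 0.64) {
    stop(sprintf(paste0("requested density is infeasible: implied sphere ",
                        "packing fraction %.3f exceeds random close packing ",
                        "(0.64) for min_distance = %.3f A"), phi, min_distance))
  }
  cl <- cell(L)
  pos <- matrix(NA_real_, n_atoms, 3)
  placed <- 0L
  for (k in seq_len(n_atoms)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, L)
      if (placed > 0L) {
        blk <- min_image_block(pos[seq_len(placed), , drop = FALSE],
                               matrix(p, 1), cl)
        if (any(blk$r < min_distance)) next
      }
      pos[k, ] <- p; placed <- k; ok <- TRUE; break
    }
    if (!ok) break
  }
  if (placed < n_atoms) {
    pos <- relax_pack(n_atoms, L, min_distance,
                      start = pos[seq_len(placed), , drop = FALSE])
    if (is.null(pos)) {
      stop("carbon box placement failed: placed ", placed, " of ", n_atoms,
           " atoms by rejection sampling and relaxation did not converge")
    }
  }
  configuration(species, pos, cl)
}

# Force-biased packing: grow the exclusion diameter towards dmin, pushing
# apart violating pairs after each growth step. Returns positions or NULL.
relax_pack <- function(n, L, dmin, start = NULL, max_sweeps = 400L) {
  pos <- matrix(stats::runif(3L * n, 0, L), n, 3)
  if (!is.null(start) && nrow(start) > 0L)
    pos[seq_len(nrow(start)), ] <- start
  cl <- cell(L)
  d_cur <- dmin / 8
  while (d_cur < dmin) {
    d_cur <- min(dmin, d_cur * 1.04)
    converged <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      blk <- min_image_block(pos, pos, cl)
      r <- blk$r; diag(r) <- Inf
      hit <- which(upper.tri(r) & r < d_cur, arr.ind = TRUE)
      if (nrow(hit) == 0L) { converged <- TRUE; break }
      disp <- matrix(0, n, 3)
      ii <- hit[, 1]; jj <- hit[, 2]
      rr <- r[hit]
      ux <- blk$dx[hit] / rr; uy <- blk$dy[hit] / rr; uz <- blk$dz[hit] / rr
      deg <- rr < 1e-9
      if (any(deg)) {
        rv <- matrix(stats::rnorm(3 * sum(deg)), ncol = 3)
        rv <- rv / sqrt(rowSums(rv^2))
        ux[deg] <- rv[, 1]; uy[deg] <- rv[, 2]; uz[deg] <- rv[, 3]
      }
      push <- 0.5 * (d_cur - rr) + 1e-3
      U <- cbind(ux, uy, uz) * push
      agg <- rowsum(rbind(U, -U), c(ii, jj))
      at <- as.integer(rownames(agg))
      disp[at, ] <- disp[at, ] + agg
      pos <- (pos + disp) %% L
    }
    if (!converged) return(NULL)
  }
  pos
}

# Uniform random rotation matrix via unit quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Pack molecules into a periodic box
#'
#' Places each molecule of a composition with a uniform random rotation
#' (unit-quaternion sampling) and a uniform random translation, accepting a
#' placement only when every atom is at least `min_separation` (minimum
#' image) from all atoms of previously placed molecules. Intramolecular
#' geometry is preserved exactly up to the rigid motion.
#'
#' @param comp an [composition()].
#' @param cell an [cell()], or `NULL` to derive a cubic cell from `density`.
#' @param density target density (g/cc) when `cell` is `NULL`.
#' @param min_separation minimum inter-molecular atom-pair distance (A).
#' @param max_attempts placement proposals per molecule.
#' @param extended allow molecules beyond the nine-seed library (e.g. CO).
#' @return an [configuration()]; attribute `molecule_id` gives the per-atom
#'   molecule index, attribute `composition` the composition.
#' @export
pack_molecules <- function(comp, cell = NULL, density = NULL,
                           min_separation = 2.0, max_attempts = 10000L,
                           extended = TRUE) {
  if (!inherits(comp, "nr_composition")) comp <- composition(comp)
  mols <- unlist(lapply(names(comp), function(nm)
    rep(nm, comp[[nm]])), use.names = FALSE)
  templates <- lapply(names(comp), seed_molecule, extended = extended)
  names(templates) <- names(comp)
  all_species <- unlist(lapply(mols, function(nm) templates[[nm]]$species),
                        use.names = FALSE)
  if (is.null(cell)) {
    if (is.null(density)) stop("give either a cell or a density")
    cell <- cell(box_edge_for_density(all_species, density))
  }
  L <- cell$edge_lengths
  pos <- matrix(NA_real_, length(all_species), 3)
  mol_id <- integer(length(all_species))
  filled <- 0L
  for (m in seq_along(mols)) {
    tpl <- templates[[mols[m]]]
    na <- nrow(tpl$positions)
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      R <- random_rotation()
      shift <- stats::runif(3) * L
      cand <- tpl$positions %*% t(R)
      cand <- sweep(cand, 2, shift, "+")
      if (filled > 0L) {
        blk <- min_image_block(pos[seq_len(filled), , drop = FALSE], cand, cell)
        if (any(blk$r < min_separation)) next
      }
      idx <- filled + seq_len(na)
      pos[idx, ] <- cand
      mol_id[idx] <- m
      filled <- filled + na
      ok <- TRUE
      break
    }
    if (!ok) {
      # dense request: sequential insertion saturated; relax rigid bodies
      res <- relax_pack_molecules(mols, templates, cell, min_separation)
      if (is.null(res)) {
        stop("packing failed for molecule ", m, " (", mols[m], ") after ",
             max_attempts, " attempts; placed ", m - 1L,
             " molecules and relaxation did not converge")
      }
      pos <- res$pos; mol_id <- res$mol_id
      break
    }
  }
  cfg <- configuration(all_species, pos, cell)
  attr(cfg, "molecule_id") <- mol_id
  attr(cfg, "composition") <- comp
  cfg
}

# Rigid-body relaxation fallback for dense molecular packing: molecules
# start on a jittered grid with random orientations; the inter-molecular
# exclusion distance is grown towards min_separation while whole molecules
# are translated apart along violating atom-pair directions, with random
# re-orientation of persistently violating molecules.
relax_pack_molecules <- function(mols, templates, cl, dmin,
                                 max_stalled_sweeps = 4000L) {
  L <- cl$edge_lengths
  nmol <- length(mols)
  k <- ceiling(nmol^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(k) - 1L, seq_len(k) - 1L,
                                seq_len(k) - 1L))
  centers <- grid[sample(k^3, nmol), , drop = FALSE] *
    rep(L / k, each = nmol)
  rot <- replicate(nmol, random_rotation(), simplify = FALSE)
  build_pos <- function() {
    pos <- vector("list", nmol)
    for (m in seq_len(nmol)) {
      tpl <- templates[[mols[m]]]
      pos[[m]] <- sweep(tpl$positions %*% t(rot[[m]]), 2, centers[m, ], "+")
    }
    do.call(rbind, pos)
  }
  mol_id <- unlist(lapply(seq_len(nmol), function(m)
    rep(m, nrow(templates[[mols[m]]]$positions))))
  same <- outer(mol_id, mol_id, "==")
  d_cur <- min(dmin, 0.8)
  sweeps <- 0L
  repeat {
    pos <- build_pos()
    blk <- min_image_block(pos, pos, cl)
    r <- blk$r
    viol <- which(upper.tri(r) & !same & r < d_cur, arr.ind = TRUE)
    if (nrow(viol) == 0L) {
      if (d_cur >= dmin) break
      d_cur <- min(dmin, d_cur * 1.02)
      sweeps <- 0L
      next
    }
    ii <- viol[, 1]; jj <- viol[, 2]; rr <- r[viol]
    ux <- blk$dx[viol] / rr; uy <- blk$dy[viol] / rr; uz <- blk$dz[viol] / rr
    deg <- !is.finite(ux) | rr < 1e-9
    if (any(deg)) {
      rv <- matrix(stats::rnorm(3 * sum(deg)), ncol = 3)
      rv <- rv / sqrt(rowSums(rv^2))
      ux[deg] <- rv[, 1]; uy[deg] <- rv[, 2]; uz[deg] <- rv[, 3]
    }
    push <- 0.3 * (d_cur - rr) + 5e-3
    U <- cbind(ux, uy, uz) * push
    agg <- rowsum(rbind(U, -U), c(mol_id[ii], mol_id[jj]))
    mids <- as.integer(rownames(agg))
    centers[mids, ] <- centers[mids, ] + agg
    centers <- centers %% rep(L, each = nmol)
    sweeps <- sweeps + 1L
    if (sweeps %% 150L == 0L) {
      for (m in unique(c(mol_id[ii], mol_id[jj])))
        rot[[m]] <- random_rotation()
    }
    if (sweeps > max_stalled_sweeps) return(NULL)
  }
  list(pos = build_pos(), mol_id = mol_id)
}

#' Composition presets from the case-study protocols
#'
#' `methane_combustion` is 100 CH4 + 200 O2 (density 0.25 g/cc in a 37.60 A
#' cubic box); `miller` is 16 H2 + 14 H2O + 14 CO + 14 NH3 + 14 CH4 (228
#' atoms, 12.1 A cubic box, 1.067 g/cc); `acetylene` is 150 C2H2 + 200 O2
#' (1,000 atoms). `scale` divides all counts (rounding up) for desk-scale
#' runs.
#'
#' @param name preset name.
#' @param scale integer divisor applied to all molecule counts.
#' @return an [composition()].
#' @export
composition_preset <- function(name = c("methane_combustion", "miller",
                                        "acetylene"), scale = 1) {
  name <- match.arg(name)
  x <- switch(name,
    methane_combustion = c(CH4 = 100, O2 = 200),
    miller = c(H2 = 16, H2O = 14, CO = 14, NH3 = 14, CH4 = 14),
    acetylene = c(C2H2 = 150, O2 = 200)
  )
  composition(ceiling(x / scale))
}

#' Policy for random nanoreactor starting systems
#'
#' @param atom_range inclusive range for the total atom count.
#' @param density_range range for the initial mass density (g/cc).
#' @param molecules candidate molecule names (default: the nine seeds).
#' @param min_separation packing separation (A).
#' @return list of class `nr_builder_policy`.
#' @export
builder_policy <- function(atom_range = c(60L, 160L),
                           density_range = c(0.2, 2.0),
                           molecules = seed_molecule_names(),
                           min_separation = 2.0) {
  stopifnot(atom_range[1] >= 1, atom_range[2] >= atom_range[1],
            density_range[1] > 0, density_range[2] >= density_range[1])
  bad <- setdiff(molecules, seed_molecule_names())
  if (length(bad))
    stop("policy molecules must be seed molecules; unknown: ",
         paste(bad, collapse = ", "))
  structure(list(atom_range = as.integer(atom_range),
                 density_range = density_range, molecules = molecules,
                 min_separation = min_separation),
            class = "nr_builder_policy")
}

#' Draw a random nanoreactor starting system
#'
#' Draws a random composition over the seed molecules until the total atom
#' count falls in the policy range, a random density in the policy range,
#' and packs the box.
#'
#' Draws whose density/composition make packing infeasible are rejected
#' and redrawn (up to `max_draws`).
#'
#' @param policy an [builder_policy()].
#' @param max_draws packing attempts with fresh draws before erroring.
#' @return an [configuration()] with `composition` attribute.
#' @export
random_nr_system <- function(policy = builder_policy(), max_draws = 10L) {
  last <- NULL
  for (d in seq_len(max_draws)) {
    res <- tryCatch(random_nr_system_once(policy), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last <- res
  }
  stop("could not build a random system after ", max_draws, " draws: ",
       conditionMessage(last))
}

random_nr_system_once <- function(policy) {
  sizes <- vapply(policy$molecules, function(nm)
    length(seed_molecule(nm)$species), integer(1))
  target <- if (policy$atom_range[1] == policy$atom_range[2])
    policy$atom_range[1]
  else sample(policy$atom_range[1]:policy$atom_range[2], 1L)
  counts <- stats::setNames(integer(length(policy$molecules)),
                            policy$molecules)
  total <- 0L
  while (TRUE) {
    pick <- if (length(policy$molecules) == 1L) policy$molecules else
      sample(policy$molecules, 1L)
    if (total + sizes[[pick]] > policy$atom_range[2]) {
      if (total >= policy$atom_range[1]) break
      fits <- sizes <= policy$atom_range[2] - total
      if (!any(fits)) {
        stop("cannot reach the policy atom range with the available molecules")
      }
      pick <- names(sizes)[fits][
        if (sum(fits) == 1L) 1L else sample(sum(fits), 1L)]
    }
    counts[[pick]] <- counts[[pick]] + 1L
    total <- total + sizes[[pick]]
    if (total >= target) break
  }
  dens <- stats::runif(1, policy$density_range[1], policy$density_range[2])
  pack_molecules(composition(counts), density = dens,
                 min_separation = policy$min_separation, extended = FALSE)
}
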