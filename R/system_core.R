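#' Orthorhombic simulation cell
#'
#' @param edge_lengths numeric length-3 vector of box edges (Angstrom).
#'   A single number is recycled to a cubic box.
#' @param periodic logical length-3 (or length-1, recycled) periodicity flags.
#' @return an object of class `nr_cell`.
#' @examples
#' cell(37.60)                  # the cubic methane-combustion box
#' cell(c(10, 12, 14), periodic = c(TRUE, TRUE, FALSE))
#' @export
cell <- function(edge_lengths, periodic = TRUE) {
  edge_lengths <- as.numeric(edge_lengths)
  if (length(edge_lengths) == 1L) edge_lengths <- rep(edge_lengths, 3L)
  if (length(edge_lengths) != 3L || !all(is.finite(edge_lengths)) ||
      any(edge_lengths <= 0)) {
    stop("cell edge lengths must be three finite positive numbers")
  }
  periodic <- rep_len(as.logical(periodic), 3L)
  structure(list(edge_lengths = edge_lengths, periodic = periodic),
            class = "nr_cell")
}

#' @export
print.nr_cell <- function(x, ...) {
  cat(sprintf("<nr_cell> %.4f x %.4f x %.4f A, periodic: %s\n",
              x$edge_lengths[1], x$edge_lengths[2], x$edge_lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param cell an [cell()] object.
#' @return volume (A^3).
#' @export
cell_volume <- function(cell) prod(cell$edge_lengths)

#' Periodic atomic configuration
#'
#' The central container: an ordered set of atoms (element symbols from
#' H, C, N, O), Cartesian positions in Angstrom and an orthorhombic cell.
#'
#' @param species character vector of element symbols.
#' @param positions numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell an [cell()] object.
#' @param wrap if `TRUE` (default), wrap fractional coordinates into `[0, 1)`
#'   along periodic directions.
#' @return an object of class `nr_config`.
#' @export
configuration <- function(species, positions, cell, wrap = TRUE) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  if (length(species) != nrow(positions))
    stop("species length (", length(species), ") does not match positions (",
         nrow(positions), " rows)")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!inherits(cell, "nr_cell")) stop("cell must be an nr_cell")
  cfg <- structure(list(species = as.character(species),
                        positions = positions, cell = cell),
                   class = "nr_config")
  if (wrap) cfg <- wrap_config(cfg)
  cfg
}

#' @export
print.nr_config <- function(x, ...) {
  comp <- table(x$species)
  cat(sprintf("<nr_config> %d atoms (%s), density %.4f g/cc\n",
              n_atoms(x),
              paste(names(comp), as.integer(comp), sep = "", collapse = " "),
              mass_density(x)))
  print(x$cell)
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config an [configuration()] object.
#' @return integer atom count.
#' @export
n_atoms <- function(config) length(config$species)

#' Wrap positions into the primary cell
#'
#' Along periodic directions, fractional coordinates are reduced into
#' `[0, 1)`. Non-periodic directions are untouched. Wrapping never changes
#' any minimum-image distance.
#'
#' @param config an [configuration()] object.
#' @return the wrapped configuration.
#' @export
wrap_config <- function(config) {
  L <- config$cell$edge_lengths
  for (d in which(config$cell$periodic)) {
    config$positions[, d] <- config$positions[, d] -
      floor(config$positions[, d] / L[d]) * L[d]
  }
  config
}

#' Minimum-image displacement and distance
#'
#' Displacement from `b` to `a` (i.e. `a - b`), reduced by the minimum-image
#' convention along periodic cell directions.
#'
#' @param a,b numeric length-3 positions (Angstrom).
#' @param cell an [cell()] object.
#' @return list with `vector` (length-3 displacement) and `distance`.
#' @export
minimum_image_displacement <- function(a, b, cell) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b))))
    stop("positions must be finite length-3 vectors")
  d <- a - b
  L <- cell$edge_lengths
  p <- cell$periodic
  d[p] <- d[p] - round(d[p] / L[p]) * L[p]
  list(vector = d, distance = sqrt(sum(d * d)))
}

# Minimum-image displacement matrix between row sets (vectorized, internal).
# Returns list(dx, dy, dz, r) each n_a x n_b.
min_image_block <- function(A, B, cell) {
  L <- cell$edge_lengths; p <- cell$periodic
  out <- vector("list", 3L)
  for (d in 1:3) {
    dd <- outer(A[, d], B[, d], "-")
    if (p[d]) dd <- dd - round(dd / L[d]) * L[d]
    out[[d]] <- dd
  }
  list(dx = out[[1]], dy = out[[2]], dz = out[[3]],
       r = sqrt(out[[1]]^2 + out[[2]]^2 + out[[3]]^2))
}

#' Mass density of a configuration
#'
#' Sum of standard atomic weights divided by the cell volume, in g/cc.
#'
#' @param config an [configuration()] object.
#' @param masses atomic-weight table, see [atomic_masses()].
#' @return density (g/cc).
#' @export
mass_density <- function(config, masses = NR_ATOMIC_MASSES) {
  if (n_atoms(config) < 1L) stop("configuration has no atoms")
  V <- cell_volume(config$cell)
  if (V <= 0) stop("zero-volume cell")
  sum(atomic_masses(config$species, masses)) * NR_AMU_G / (V * 1e-24)
}

#' Neighbor pairs within a cutoff
#'
#' All unordered atom pairs whose minimum-image distance is strictly below
#' `cutoff`. Uses a cell-linked-list search for large systems and a
#' brute-force minimum-image scan below `brute_below` atoms; the two
#' routes agree exactly.
#'
#' For periodic directions the minimum-image convention is only valid when
#' `cutoff <= L/2`; beyond that the function errors unless
#' `multi_image = TRUE`, in which case explicit periodic images are
#' enumerated and the *minimum* image distance is still reported per pair.
#'
#' @param config an [configuration()] object.
#' @param cutoff distance cutoff (Angstrom), `>= 0`.
#' @param method `"auto"`, `"brute"` or `"cell"`.
#' @param brute_below atom count below which brute force is used in
#'   `"auto"` mode.
#' @param multi_image allow cutoffs beyond half the shortest periodic edge.
#' @return data.frame with columns `i`, `j` (`i < j`) and `dist`.
#' @export
neighbor_pairs <- function(config, cutoff, method = c("auto", "brute", "cell"),
                           brute_below = 200L, multi_image = FALSE) {
  method <- match.arg(method)
  if (!is.finite(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  N <- n_atoms(config)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (N < 2L || cutoff == 0) return(empty)
  L <- config$cell$edge_lengths
  p <- config$cell$periodic
  half_ok <- !any(p) || cutoff <= min(L[p]) / 2
  if (!half_ok && !multi_image) {
    stop("cutoff (", cutoff, " A) exceeds half the shortest periodic edge (",
         signif(min(L[p]) / 2, 6),
         " A): enlarge the box or set multi_image = TRUE")
  }
  if (!half_ok) {
    pl <- pair_list_images(config, cutoff)
    if (length(pl$i) == 0L) return(empty)
    keep <- pl$i != pl$j
    a <- pmin(pl$i, pl$j)[keep]; b <- pmax(pl$i, pl$j)[keep]
    r <- pl$r[keep]
    key <- a + N * b
    ord <- order(key, r)
    a <- a[ord]; b <- b[ord]; r <- r[ord]; key <- key[ord]
    first <- !duplicated(key)
    out <- data.frame(i = a[first], j = b[first], dist = r[first])
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  use_brute <- method == "brute" || (method == "auto" && N < brute_below)
  if (use_brute) {
    blk <- min_image_block(config$positions, config$positions, config$cell)
    r <- blk$r
    idx <- which(upper.tri(r) & r < cutoff, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(empty)
    out <- data.frame(i = idx[, 1], j = idx[, 2], dist = r[idx])
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  cell_list_pairs(config, cutoff)
}

# Cell-linked-list neighbor search (orthorhombic, minimum image).
cell_list_pairs <- function(config, cutoff) {
  N <- n_atoms(config)
  L <- config$cell$edge_lengths
  per <- config$cell$periodic
  nb <- pmax(1L, floor(L / cutoff))
  # need >= 3 bins along periodic dims for the 27-stencil to be exact
  if (any(nb[per] < 3L)) {
    return(neighbor_pairs(config, cutoff, method = "brute"))
  }
  pos <- config$positions
  frac <- sweep(pos, 2, L, "/")
  frac <- frac - floor(frac)
  bin <- pmin(floor(sweep(frac, 2, nb, "*")), matrix(rep(nb - 1L, each = N), N))
  storage.mode(bin) <- "integer"
  bid <- bin[, 1] + nb[1] * (bin[, 2] + nb[2] * bin[, 3])
  atoms_by_bin <- split(seq_len(N), bid)
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  occupied <- as.integer(names(atoms_by_bin))
  for (b in occupied) {
    bx <- b %% nb[1]; by <- (b %/% nb[1]) %% nb[2]; bz <- b %/% (nb[1] * nb[2])
    ai <- atoms_by_bin[[as.character(b)]]
    for (s in seq_len(nrow(shifts))) {
      cx <- bx + shifts[s, 1]; cy <- by + shifts[s, 2]; cz <- bz + shifts[s, 3]
      ok <- TRUE
      for (d in 1:3) {
        v <- c(cx, cy, cz)[d]
        if (v < 0 || v >= nb[d]) {
          if (per[d]) next
          ok <- FALSE; break
        }
      }
      if (!ok) next
      cx <- cx %% nb[1]; cy <- cy %% nb[2]; cz <- cz %% nb[3]
      nbid <- cx + nb[1] * (cy + nb[2] * cz)
      if (nbid < b) next
      aj <- atoms_by_bin[[as.character(nbid)]]
      if (is.null(aj)) next
      blk <- min_image_block(pos[ai, , drop = FALSE], pos[aj, , drop = FALSE],
                             config$cell)
      hit <- which(blk$r < cutoff, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      ii <- ai[hit[, 1]]; jj <- aj[hit[, 2]]
      # canonical order; atom indices need not follow bin order, so pairs
      # are deduplicated at the end rather than filtered here
      keep <- ii != jj
      res_i <- c(res_i, pmin(ii, jj)[keep])
      res_j <- c(res_j, pmax(ii, jj)[keep])
      res_d <- c(res_d, blk$r[hit][keep])
    }
  }
  out <- data.frame(i = res_i, j = res_j, dist = res_d)
  out <- out[!duplicated(out[, 1:2]), , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Directed pair list with explicit image shifts; used internally by the
# descriptors and the toy potential so that small boxes (L < 2*cutoff)
# are handled correctly. Returns a plain list of vectors (i, j, dx, dy,
# dz, r) with one entry per (ordered pair, image) at r < cutoff; i == j
# entries are periodic self-images. dx/dy/dz point from atom i to j.
pair_list_images <- function(config, cutoff) {
  N <- n_atoms(config)
  L <- config$cell$edge_lengths
  per <- config$cell$periodic
  nrep <- ifelse(per, pmax(1L, ceiling(cutoff / L)), 0L)
  reps <- expand.grid(sx = -nrep[1]:nrep[1], sy = -nrep[2]:nrep[2],
                      sz = -nrep[3]:nrep[3])
  pos <- config$positions
  res <- vector("list", nrow(reps))
  for (k in seq_len(nrow(reps))) {
    shift <- c(reps$sx[k] * L[1], reps$sy[k] * L[2], reps$sz[k] * L[3])
    B <- sweep(pos, 2, shift, "+")
    dx <- outer(pos[, 1], B[, 1], "-")
    dy <- outer(pos[, 2], B[, 2], "-")
    dz <- outer(pos[, 3], B[, 3], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(r < cutoff & r > 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0L) { res[[k]] <- NULL; next }
    res[[k]] <- list(i = hit[, 1], j = hit[, 2],
                     dx = -dx[hit], dy = -dy[hit], dz = -dz[hit],
                     r = r[hit])
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(list(i = integer(), j = integer(), dx = numeric(),
                dy = numeric(), dz = numeric(), r = numeric()))
  list(i = unlist(lapply(res, `[[`, "i"), use.names = FALSE),
       j = unlist(lapply(res, `[[`, "j"), use.names = FALSE),
       dx = unlist(lapply(res, `[[`, "dx"), use.names = FALSE),
       dy = unlist(lapply(res, `[[`, "dy"), use.names = FALSE),
       dz = unlist(lapply(res, `[[`, "dz"), use.names = FALSE),
       r = unlist(lapply(res, `[[`, "r"), use.names = FALSE))
}

# Directed neighbor list for force/descriptor work. Chooses minimum image
# when safe, explicit images otherwise. Plain list of vectors; dx/dy/dz
# point from atom i to neighbor j (r_j - r_i).
directed_pairs <- function(config, cutoff) {
  L <- config$cell$edge_lengths
  per <- config$cell$periodic
  if (any(per) && cutoff > min(L[per]) / 2) {
    return(pair_list_images(config, cutoff))
  }
  pos <- config$positions
  blk <- min_image_block(pos, pos, config$cell)
  hit <- which(upper.tri(blk$r) & blk$r < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(list(i = integer(), j = integer(), dx = numeric(),
                dy = numeric(), dz = numeric(), r = numeric()))
  ii <- hit[, 1]; jj <- hit[, 2]
  # blk dx = pos_i - pos_j; displacement i->j is the negative
  dx <- -blk$dx[hit]; dy <- -blk$dy[hit]; dz <- -blk$dz[hit]
  r <- blk$r[hit]
  list(i = c(ii, jj), j = c(jj, ii),
       dx = c(dx, -dx), dy = c(dy, -dy), dz = c(dz, -dz),
       r = c(r, r))
}

#' Trajectory: an ordered sequence of configurations
#'
#' @param frames list of [configuration()] objects sharing the species
#'   ordering.
#' @param times numeric simulation times (fs), strictly increasing.
#' @param scalars optional data.frame of per-frame scalars (e.g.
#'   `temperature`, `density`, `energy`).
#' @return an object of class `nr_trajectory`.
#' @export
trajectory <- function(frames, times, scalars = NULL) {
  if (length(frames) != length(times))
    stop("frames and times must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (length(frames) > 1L) {
    sp <- frames[[1]]$species
    same <- vapply(frames, function(f) identical(f$species, sp), logical(1))
    if (!all(same)) stop("all frames must share the species ordering")
  }
  if (!is.null(scalars)) {
    scalars <- as.data.frame(scalars)
    if (nrow(scalars) != length(frames))
      stop("scalars must have one row per frame")
  }
  structure(list(frames = frames, times = as.numeric(times),
                 scalars = scalars),
            class = "nr_trajectory")
}

#' @export
print.nr_trajectory <- function(x, ...) {
  nf <- length(x$frames)
  cat(sprintf("<nr_trajectory> %d frames, %d atoms, t = %.1f .. %.1f fs\n",
              nf, if (nf) n_atoms(x$frames[[1]]) else 0L,
              if (nf) x$times[1] else NA, if (nf) x$times[nf] else NA))
  invisible(x)
}

#' @export
length.nr_trajectory <- function(x) length(x$frames)

#' Labeled training sample
#'
#' A configuration together with its reference total potential energy
#' (kcal/mol) and per-atom forces (kcal/mol/A).
#'
#' @param config an [configuration()] object.
#' @param energy total potential energy (kcal/mol).
#' @param forces N x 3 numeric matrix (kcal/mol/A).
#' @return an object of class `nr_sample`.
#' @export
labeled_sample <- function(config, energy, forces) {
  forces <- as.matrix(forces)
  if (!identical(dim(forces), c(n_atoms(config), 3L)) &&
      !(nrow(forces) == n_atoms(config) && ncol(forces) == 3L))
    stop("forces must be N x 3")
  if (!is.finite(energy)) stop("energy must be finite")
  structure(list(config = config, energy = as.numeric(energy),
                 forces = forces),
            class = "nr_sample")
}

#' @export
print.nr_sample <- function(x, ...) {
  cat(sprintf("<nr_sample> %d atoms, E = %.4f kcal/mol\n",
              n_atoms(x$config), x$energy))
  invisible(x)
}
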