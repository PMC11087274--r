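#' Diamond-lattice fixture
#'
#' A periodic diamond-cubic carbon crystal: conventional cell parameter
#' `a`, 8 atoms per conventional cell, replicated `replicas` times along
#' each axis. Nearest-neighbor distance is `a * sqrt(3) / 4`; every atom
#' has exactly 4 nearest neighbors.
#'
#' @param a conventional cell parameter (A); 3.567 for diamond.
#' @param replicas integer replications per axis (scalar or length 3).
#' @return an [configuration()].
#' @export
diamond_lattice <- function(a = 3.567, replicas = 2L) {
  replicas <- rep_len(as.integer(replicas), 3L)
  if (any(replicas < 1L)) stop("replicas must be >= 1")
  basis <- rbind(
    c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0),
    c(.25, .25, .25), c(.25, .75, .75), c(.75, .25, .75), c(.75, .75, .25))
  cells <- expand.grid(x = seq_len(replicas[1]) - 1L,
                       y = seq_len(replicas[2]) - 1L,
                       z = seq_len(replicas[3]) - 1L)
  pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k)
    sweep(basis, 2, as.numeric(cells[k, ]), "+")))
  pos <- pos * a
  configuration(rep("C", nrow(pos)), pos, cell(a * replicas))
}

#' Hexagonal-sheet fixture
#'
#' A planar strip of `n_rings` edge-fused carbon hexagons (acene-like),
#' bond length `d`. Its bond graph has exactly `n_rings` independent
#' cycles, all six-membered.
#'
#' @param n_rings number of fused hexagons (`>= 1`).
#' @param d C-C bond length (A).
#' @param vacuum padding around the sheet in the non-periodic box (A).
#' @return an [configuration()] with a large non-periodic cell.
#' @export
hexagonal_sheet <- function(n_rings = 3L, d = 1.42, vacuum = 10) {
  stopifnot(n_rings >= 1L)
  centers <- cbind((seq_len(n_rings) - 1L) * sqrt(3) * d, 0)
  ang <- pi / 6 + (0:5) * pi / 3      # 30, 90, ..., 330 degrees
  verts <- do.call(rbind, lapply(seq_len(n_rings), function(k)
    cbind(centers[k, 1] + d * cos(ang), centers[k, 2] + d * sin(ang))))
  verts <- unique(round(verts, 6))
  pos <- cbind(verts, 0)
  pos <- sweep(pos, 2, apply(pos, 2, min), "-") + vacuum / 2
  span <- apply(pos, 2, max) + vacuum / 2
  configuration(rep("C", nrow(pos)), pos, cell(span, periodic = FALSE))
}

#' Scripted toy reaction trajectory
#'
#' Builds a two-phase trajectory from a reaction script of the form
#' `"2H2+O2->2H2O@3"`: frames before frame 3 contain the reactant
#' molecules (far apart, unbonded between molecules), frames from 3 on
#' contain the products. Spectator molecules can be given via `spectators`.
#' The fixture provides exact ground truth for species tracking.
#'
#' @param script reaction string `"<counts+formulas> -> <counts+formulas> @ frame"`.
#' @param n_frames total frames (`>=` the event frame).
#' @param spectators optional [composition()] present in every frame.
#' @param spacing center-to-center molecule spacing (A).
#' @param dt_fs time between frames (fs).
#' @return an [trajectory()].
#' @export
reaction_toy_trajectory <- function(script, n_frames = 6L, spectators = NULL,
                                    spacing = 6, dt_fs = 50) {
  m <- regmatches(script,
                  regexec("^\\s*(.+?)\\s*->\\s*(.+?)\\s*@\\s*(\\d+)\\s*$",
                          script))[[1]]
  if (length(m) != 4L)
    stop("cannot parse reaction script: ", script)
  parse_side <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    counts <- c()
    for (tm in terms) {
      tm <- trimws(tm)
      cm <- regmatches(tm, regexec("^(\\d*)\\s*([A-Za-z0-9]+)$", tm))[[1]]
      if (length(cm) != 3L) stop("cannot parse reaction term: ", tm)
      n <- if (nzchar(cm[2])) as.integer(cm[2]) else 1L
      counts[cm[3]] <- (if (cm[3] %in% names(counts)) counts[[cm[3]]] else 0L) + n
    }
    composition(counts)
  }
  before <- parse_side(m[2]); after <- parse_side(m[3])
  event <- as.integer(m[4])
  if (event < 1L || event > n_frames)
    stop("event frame must lie within 1..n_frames")
  add_spec <- function(comp) {
    if (is.null(spectators)) return(comp)
    all <- stats::setNames(as.integer(comp), names(comp))
    for (nm in names(spectators))
      all[nm] <- (if (nm %in% names(all)) all[[nm]] else 0L) + spectators[[nm]]
    composition(all)
  }
  before <- add_spec(before); after <- add_spec(after)
  build_frame <- function(comp) {
    mols <- unlist(lapply(names(comp), function(nm) rep(nm, comp[[nm]])))
    k <- ceiling(length(mols)^(1 / 3))
    grid <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1),
                                  z = 0:(k - 1)))[seq_along(mols), ,
                                                  drop = FALSE] * spacing
    sp <- character(0); pos <- NULL
    for (i in seq_along(mols)) {
      tpl <- seed_molecule(mols[i], extended = TRUE)
      sp <- c(sp, tpl$species)
      pos <- rbind(pos, sweep(tpl$positions, 2, grid[i, ] + spacing / 2, "+"))
    }
    ord <- order(sp)        # element-sorted so phases share the ordering
    configuration(sp[ord], pos[ord, , drop = FALSE],
                  cell(k * spacing, periodic = TRUE))
  }
  f_before <- build_frame(before)
  f_after <- build_frame(after)
  if (!identical(f_before$species, f_after$species))
    stop("reaction script is not atom-balanced: ", script)
  frames <- lapply(seq_len(n_frames), function(f)
    if (f < event) f_before else f_after)
  tr <- trajectory(frames, (seq_len(n_frames) - 1) * dt_fs)
  attr(tr, "event_frame") <- event
  tr
}
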