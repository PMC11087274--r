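#' Symmetry-function descriptor parameters
#'
#' Behler-Parrinello-style atomic environment descriptors in the ANI
#' variant: element-pair-resolved radial terms
#' \eqn{G^R_s = \sum_j e^{-\eta (r_{ij} - R_s)^2} f_c(r_{ij})}
#' and element-triple-resolved angular terms
#' \eqn{G^A = 2^{1-\zeta} \sum_{j<k} (1 + \cos(\theta - \theta_s))^\zeta
#'   e^{-\eta (\bar r - R_s)^2} f_c(r_{ij}) f_c(r_{ik})}
#' with \eqn{\bar r = (r_{ij} + r_{ik})/2} and the cosine cutoff
#' [cutoff_fn()]. Following the reference ANI implementation, the angle is
#' computed as \eqn{\theta = \arccos(0.95\cos\theta)} so that its gradient
#' stays bounded at collinear geometries.
#'
#' Default cutoffs are 5.2 A (radial) and 3.5 A (angular). The shell sets
#' are small evenly spaced grids sized for desk-scale training and fully
#' configurable.
#'
#' @param elements element symbols the descriptor resolves (order fixes the
#'   layout of the environment vector).
#' @param radial_cutoff,angular_cutoff cutoffs (A);
#'   `angular_cutoff <= radial_cutoff`.
#' @param radial_centers radial shell centers R_s (A).
#' @param radial_eta radial Gaussian width eta (1/A^2), single value.
#' @param angular_sections number of theta_s sections on (0, pi).
#' @param angular_centers radial centers for the angular part (A).
#' @param angular_eta,zeta angular widths/exponent.
#' @return list of class `nr_descriptor_params`.
#' @export
descriptor_params <- function(elements = c("H", "C", "N", "O"),
                              radial_cutoff = 5.2, angular_cutoff = 3.5,
                              radial_centers = seq(0.7, 4.6, length.out = 8),
                              radial_eta = 4.0,
                              angular_sections = 4,
                              angular_centers = c(0.9, 2.2),
                              angular_eta = 3.0, zeta = 8.0) {
  if (radial_cutoff <= 0 || angular_cutoff <= 0)
    stop("cutoffs must be > 0")
  if (angular_cutoff > radial_cutoff)
    stop("angular_cutoff must not exceed radial_cutoff")
  if (length(radial_centers) < 1L || length(angular_centers) < 1L)
    stop("at least one radial and one angular shell is required")
  elements <- unique(as.character(elements))
  theta_s <- pi * (2 * seq_len(angular_sections) - 1) / (2 * angular_sections)
  ne <- length(elements)
  pairs <- expand.grid(a = seq_len(ne), b = seq_len(ne))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  p <- structure(list(
    elements = elements,
    radial_cutoff = radial_cutoff, angular_cutoff = angular_cutoff,
    radial_centers = radial_centers, radial_eta = radial_eta,
    theta_s = theta_s, angular_centers = angular_centers,
    angular_eta = angular_eta, zeta = zeta,
    elem_pairs = pairs
  ), class = "nr_descriptor_params")
  p$n_radial <- ne * length(radial_centers)
  p$n_angular <- nrow(pairs) * length(theta_s) * length(angular_centers)
  p$length <- p$n_radial + p$n_angular
  p
}

#' @export
print.nr_descriptor_params <- function(x, ...) {
  cat(sprintf(
    "<nr_descriptor_params> elements %s, rc 5.2-> %.2f/%.2f A, length %d\n",
    paste(x$elements, collapse = ","), x$radial_cutoff, x$angular_cutoff,
    x$length))
  invisible(x)
}

#' Cosine cutoff function
#'
#' `0.5 cos(pi r / r_c) + 0.5` for `r < r_c`, zero at and beyond `r_c`;
#' continuous and monotone non-increasing on `[0, r_c]`.
#'
#' @param r distances (A), `>= 0`.
#' @param r_c cutoff (A).
#' @return values in `[0, 1]`.
#' @export
cutoff_fn <- function(r, r_c) {
  ifelse(r < r_c, 0.5 * cos(pi * r / r_c) + 0.5, 0)
}

# derivative of cutoff_fn for r < r_c (0 beyond)
cutoff_fn_d <- function(r, r_c) {
  ifelse(r < r_c, -0.5 * pi / r_c * sin(pi * r / r_c), 0)
}

# Column index helpers -------------------------------------------------------

# radial block: for neighbor element e (1..ne), shells s (1..S):
# col = (e - 1) * S + s
radial_col <- function(e_idx, s_idx, S) (e_idx - 1L) * S + s_idx

# angular block: for unordered element pair p (1..np), combo q (1..Q):
# col = n_radial + (p - 1) * Q + q
angular_pair_index <- function(ea, eb, ne) {
  a <- pmin(ea, eb); b <- pmax(ea, eb)
  # position of (a, b), a <= b, in column-major upper-triangular enumeration
  # consistent with descriptor_params$elem_pairs ordering
  (b - 1L) * b %/% 2L + a
}

# scatter-add vals into X at (ii, cc) with duplicate accumulation
scatter_add <- function(X, ii, cc, vals) {
  key <- ii + (cc - 1) * nrow(X)
  acc <- rowsum(vals, key)
  at <- as.numeric(rownames(acc))
  X[at] <- X[at] + acc[, 1]
  X
}

# Full descriptor evaluation -------------------------------------------------

# Computes the N x D descriptor matrix and, when gradients = TRUE, the pair
# and triple derivative tables needed for analytic forces:
#   pairs:   i, j, ux, uy, uz (unit i->j), r, g[p, S], dg[p, S] per shell
#   triples: center i, ends j, k, geometry partials and per-combo G/dG terms
descriptor_set <- function(config, params, gradients = FALSE) {
  N <- n_atoms(config)
  ne <- length(params$elements)
  S <- length(params$radial_centers)
  elem_idx <- match(config$species, params$elements)
  if (anyNA(elem_idx))
    stop("configuration contains elements outside the descriptor set: ",
         paste(setdiff(unique(config$species), params$elements),
               collapse = ", "))
  X <- matrix(0, N, params$length)
  dp <- directed_pairs(config, params$radial_cutoff)
  out <- list(X = X, pairs = NULL, triples = NULL, elem_idx = elem_idx,
              params = params)
  np_dir <- length(dp$i)
  if (np_dir == 0L) return(out)

  # --- radial part
  r <- dp$r
  fc <- cutoff_fn(r, params$radial_cutoff)
  dfc <- cutoff_fn_d(r, params$radial_cutoff)
  eta <- params$radial_eta
  G <- matrix(0, np_dir, S)
  dG <- matrix(0, np_dir, S)
  for (s in seq_len(S)) {
    dr <- r - params$radial_centers[s]
    ex <- exp(-eta * dr * dr)
    G[, s] <- ex * fc
    dG[, s] <- ex * (-2 * eta * dr * fc + dfc)
  }
  cols <- radial_col(elem_idx[dp$j], rep(1L, np_dir), S)
  for (s in seq_len(S)) {
    X <- scatter_add(X, dp$i, cols + (s - 1L), G[, s])
  }

  if (gradients) {
    out$pairs <- list(i = dp$i, j = dp$j,
                      ux = dp$dx / r, uy = dp$dy / r, uz = dp$dz / r,
                      r = r, G = G, dG = dG,
                      jcol_base = (elem_idx[dp$j] - 1L) * S)
  }

  # --- angular part
  rc_a <- params$angular_cutoff
  within_a <- which(dp$r < rc_a)
  if (length(within_a) >= 2L) {
    # neighbor lists per center from the directed pair subset
    sub <- lapply(dp, `[`, within_a)
    ord <- order(sub$i)
    sub <- lapply(sub, `[`, ord)
    counts <- tabulate(sub$i, nbins = N)
    ends <- cumsum(counts)
    tri_i <- integer(0); tj <- integer(0); tk <- integer(0)
    for (ci in which(counts >= 2L)) {
      idxs <- (ends[ci] - counts[ci] + 1L):ends[ci]
      cmb <- utils::combn(idxs, 2L)
      tri_i <- c(tri_i, rep(ci, ncol(cmb)))
      tj <- c(tj, cmb[1, ]); tk <- c(tk, cmb[2, ])
    }
    if (length(tri_i)) {
      v1 <- cbind(sub$dx[tj], sub$dy[tj], sub$dz[tj])
      v2 <- cbind(sub$dx[tk], sub$dy[tk], sub$dz[tk])
      r1 <- sub$r[tj]; r2 <- sub$r[tk]
      cth <- rowSums(v1 * v2) / (r1 * r2)
      cth <- pmin(1, pmax(-1, cth))
      theta <- acos(0.95 * cth)
      fc1 <- cutoff_fn(r1, rc_a); fc2 <- cutoff_fn(r2, rc_a)
      dfc1 <- cutoff_fn_d(r1, rc_a); dfc2 <- cutoff_fn_d(r2, rc_a)
      rbar <- 0.5 * (r1 + r2)
      ea <- params$zeta; eta_a <- params$angular_eta
      pr_idx <- angular_pair_index(elem_idx[sub$j[tj]], elem_idx[sub$j[tk]], ne)
      Q <- length(params$theta_s) * length(params$angular_centers)
      ncomb <- 0L
      tG <- matrix(0, length(tri_i), Q)
      tdG_th <- matrix(0, length(tri_i), Q)  # dG/dtheta
      tdG_r <- matrix(0, length(tri_i), Q)   # dG/drbar (radial gaussian part)
      for (ts in params$theta_s) for (rs in params$angular_centers) {
        ncomb <- ncomb + 1L
        ang <- (1 + cos(theta - ts))^ea
        dang <- -ea * (1 + cos(theta - ts))^(ea - 1) * sin(theta - ts)
        drb <- rbar - rs
        rad <- exp(-eta_a * drb * drb)
        pref <- 2^(1 - ea)
        tG[, ncomb] <- pref * ang * rad
        tdG_th[, ncomb] <- pref * dang * rad
        tdG_r[, ncomb] <- pref * ang * rad * (-2 * eta_a * drb)
      }
      # accumulate X (with both cutoff factors)
      fcp <- fc1 * fc2
      colbase <- params$n_radial + (pr_idx - 1L) * Q
      for (q in seq_len(Q)) {
        X <- scatter_add(X, tri_i, colbase + q, tG[, q] * fcp)
      }
      if (gradients) {
        sinth <- sin(theta)
        # dtheta/dcth with the 0.95 regularization (bounded everywhere)
        dth_dc <- -0.95 / sqrt(1 - (0.95 * cth)^2)
        out$triples <- list(
          i = tri_i, j = sub$j[tj], k = sub$j[tk],
          v1 = v1, v2 = v2, r1 = r1, r2 = r2, cth = cth,
          fc1 = fc1, fc2 = fc2, dfc1 = dfc1, dfc2 = dfc2,
          dth_dc = dth_dc,
          G = tG, dG_th = tdG_th, dG_r = tdG_r,
          colbase = colbase, Q = Q
        )
      }
    }
  }
  out$X <- X
  out
}

#' Atomic environment vector
#'
#' The concatenated radial (element-pair resolved) and angular
#' (element-triple resolved) symmetry-function vector of one atom. The
#' length depends only on the parameters, not on the configuration.
#' Periodic images are handled explicitly, so small cells are valid.
#'
#' @param config an [configuration()].
#' @param atom_index atom index (1-based).
#' @param params an [descriptor_params()].
#' @return numeric vector of length `params$length`.
#' @export
environment_vector <- function(config, atom_index, params = descriptor_params()) {
  if (atom_index < 1L || atom_index > n_atoms(config))
    stop("atom_index out of range")
  ds <- descriptor_set(config, params)
  ds$X[atom_index, ]
}

#' All environment vectors of a configuration
#'
#' @inheritParams environment_vector
#' @return N x D matrix, one row per atom.
#' @export
environment_matrix <- function(config, params = descriptor_params()) {
  descriptor_set(config, params)$X
}
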