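#' Calculator contract
#'
#' A calculator is the pluggable labeler/driver interface: a list with
#' `evaluate(config) -> list(energy, forces)` (kcal/mol, kcal/mol/A),
#' `elements` (supported symbols) and `cutoff` (interaction range, A).
#' Energies must be invariant under rigid translation and under permutation
#' of like elements, with forces the negative configuration-gradient.
#'
#' The reference labeler of the original workflow is periodic DFT
#' (CP2K: unrestricted KS-DFT, BLYP functional, TZV2P basis, GTH
#' pseudopotentials, D3 dispersion with zero damping, 600/60 Ry plane-wave/
#' Gaussian cutoffs, singlet spin for the whole box). This package never
#' runs DFT; an external labeler can be attached through the
#' directory-exchange adapter (see the methods vignette) or any function
#' honouring this contract. The built-in stand-in is [toy_potential()].
#'
#' @param evaluate function taking an [configuration()] and returning
#'   `list(energy =, forces =)`.
#' @param elements supported element symbols.
#' @param cutoff interaction cutoff (A).
#' @param label short identifier used in provenance records.
#' @return an object of class `nr_calculator`.
#' @export
calculator <- function(evaluate, elements, cutoff, label = "custom") {
  stopifnot(is.function(evaluate))
  structure(list(evaluate = evaluate, elements = elements, cutoff = cutoff,
                 label = label),
            class = "nr_calculator")
}

#' @export
print.nr_calculator <- function(x, ...) {
  cat(sprintf("<nr_calculator> %s: elements %s, cutoff %.2f A\n",
              x$label, paste(x$elements, collapse = ","), x$cutoff))
  invisible(x)
}

# Default pair parameters. Equilibrium lengths are near the seed-molecule
# bond lengths (C-H ~ 1.1, C-C ~ 1.4, O-H ~ 1.0 A); well depths are kept
# moderate (tens of kcal/mol) so bonds persist at room temperature yet
# break under nanoreactor conditions, and each pair carries a stiff
# inverse-power core that prevents the unphysical sub-equilibrium
# compression a purely pairwise well would otherwise allow. These are
# fixtures for desk-scale work, not fitted to any reference data.
.toy_default_params <- local({
  pairs <- list(
    HH = c(De = 35, r0 = 0.74, a = 2.2),
    HC = c(De = 38, r0 = 1.09, a = 2.2),
    HN = c(De = 36, r0 = 1.01, a = 2.2),
    HO = c(De = 40, r0 = 0.96, a = 2.2),
    CC = c(De = 48, r0 = 1.40, a = 2.2),
    CN = c(De = 50, r0 = 1.30, a = 2.2),
    CO = c(De = 54, r0 = 1.25, a = 2.2),
    NN = c(De = 58, r0 = 1.15, a = 2.2),
    NO = c(De = 46, r0 = 1.20, a = 2.2),
    OO = c(De = 42, r0 = 1.25, a = 2.2)
  )
  pairs
})

toy_pair_key <- function(e1, e2) {
  ord <- c(H = 1L, C = 2L, N = 3L, O = 4L)
  k1 <- pmin(ord[e1], ord[e2]); k2 <- pmax(ord[e1], ord[e2])
  nm <- names(ord)
  paste0(nm[k1], nm[k2])
}

#' Built-in toy reactive potential
#'
#' A smooth pairwise reactive potential used as the desk-scale labeler: for
#' each element pair a Morse well plus a stiff inverse-power core,
#' \eqn{V(r) = D_e [(1 - e^{-a (r - r_0)})^2 - 1] +
#'   \epsilon_c (0.8 r_0 / r)^{12}},
#' multiplied by a cosine switching function that takes the interaction
#' smoothly to zero at the cutoff. The core keeps dense many-neighbor
#' clusters from compressing below the pair equilibrium (a known artifact
#' of unsaturated pairwise wells). Bonds can form and break freely (no
#' fixed topology); energy and forces are continuous everywhere. This is a
#' self-contained model potential: it makes no claim of chemical
#' accuracy.
#'
#' @param params named list of per-pair parameter vectors
#'   `c(De =, r0 =, a =)` with names like `"CH"`; defaults cover all
#'   H/C/N/O pairs.
#' @param cutoff switching cutoff (A).
#' @param min_distance hard floor below which evaluation errors (overlap).
#' @return an `nr_calculator`.
#' @export
toy_potential <- function(params = NULL, cutoff = 3.2, min_distance = 0.1) {
  if (is.null(params)) params <- .toy_default_params
  ev <- function(config) {
    toy_energy_forces(config, params = params, cutoff = cutoff,
                      min_distance = min_distance)
  }
  calculator(ev, elements = c("H", "C", "N", "O"), cutoff = cutoff,
             label = "toy")
}

#' Toy-potential energy and forces
#'
#' @param config an [configuration()] with species among H, C, N, O.
#' @param params,cutoff,min_distance see [toy_potential()].
#' @return list with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
toy_energy_forces <- function(config, params = NULL, cutoff = 3.2,
                              min_distance = 0.1) {
  if (is.null(params)) params <- .toy_default_params
  bad <- setdiff(unique(config$species), c("H", "C", "N", "O"))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  N <- n_atoms(config)
  forces <- matrix(0, N, 3)
  if (N < 2L) return(list(energy = 0, forces = forces))
  dp <- directed_pairs(config, cutoff)
  if (length(dp$i) == 0L) return(list(energy = 0, forces = forces))
  if (any(dp$r < min_distance)) {
    k <- which.min(dp$r)
    stop(sprintf("overlapping atoms %d and %d (distance %.4f A < %.2f A)",
                 dp$i[k], dp$j[k], dp$r[k], min_distance))
  }
  key <- toy_pair_key(config$species[dp$i], config$species[dp$j])
  pm <- do.call(rbind, params)[key, , drop = FALSE]
  r <- dp$r
  ex <- exp(-pm[, "a"] * (r - pm[, "r0"]))
  core_r <- 0.8 * pm[, "r0"]
  eps_c <- 20
  core <- eps_c * (core_r / r)^12
  Vm <- pm[, "De"] * ((1 - ex)^2 - 1) + core
  dVm <- 2 * pm[, "De"] * pm[, "a"] * (1 - ex) * ex - 12 * core / r
  # cosine switch, 1 at r = 0, 0 at cutoff
  s <- 0.5 * cos(pi * r / cutoff) + 0.5
  ds <- -0.5 * pi / cutoff * sin(pi * r / cutoff)
  V <- Vm * s
  dV <- dVm * s + Vm * ds
  energy <- 0.5 * sum(V)      # directed list counts every pair twice
  # force on atom i from pair (i -> j): -dV/dr * d r/d r_i = +dV * u_ij
  u <- cbind(dp$dx, dp$dy, dp$dz) / r
  contrib <- u * dV
  agg <- rowsum(contrib, dp$i)
  at <- as.integer(rownames(agg))
  forces[at, ] <- forces[at, ] + agg
  list(energy = energy, forces = forces)
}

#' Label configurations with a calculator
#'
#' Runs single-point evaluations on a batch, producing one
#' [labeled_sample()] per input in order. Per-item failures (for example
#' overlapping atoms) are recorded and do not abort the batch, mirroring
#' the tolerance of reference-labeler non-convergence in active-learning
#' practice.
#'
#' @param configs list of [configuration()] objects.
#' @param calc an `nr_calculator`.
#' @return list with `samples` (successful [labeled_sample()]s),
#'   `failed` (integer indices into `configs`) and `reasons` (messages).
#' @export
label_configurations <- function(configs, calc) {
  samples <- list(); failed <- integer(0); reasons <- character(0)
  for (k in seq_along(configs)) {
    res <- tryCatch(calc$evaluate(configs[[k]]), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, k)
      reasons <- c(reasons, conditionMessage(res))
    } else {
      samples[[length(samples) + 1L]] <-
        labeled_sample(configs[[k]], res$energy, res$forces)
    }
  }
  list(samples = samples, failed = failed, reasons = reasons)
}
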