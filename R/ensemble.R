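#' Training configuration for the ensemble
#'
#' Members are per-element ridge regressors on a hybrid feature map: the
#' standardized environment vector taken linearly (the radial descriptor
#' block is an RBF expansion of the local pair distribution, so linear
#' terms already express near-pairwise energetics) plus `n_features`
#' random Fourier features `cos(W_e x_i + c_e)` for nonlinear
#' corrections, with `W_e`, `c_e` fixed random draws per member. The
#' trained coefficients enter energies and forces linearly, so the joint
#' weighted energy+force loss is solved exactly in closed form.
#' Because the solve is closed-form, the learning-rate annealing settings
#' (`stop_lr`, `anneal_factor`, `max_epochs`) are convergence bookkeeping
#' only: a fit always terminates "converged".
#'
#' @param energy_weight weight of the per-atom-normalized energy term in
#'   the loss.
#' @param force_weight weight of the force term.
#' @param force_scale soft force scale (kcal/mol/A): force residual rows
#'   are down-weighted by `1 / (1 + (f/force_scale)^2)` so that the very
#'   large forces of hot, compressed configurations inform the fit
#'   without dominating the gentle near-equilibrium region.
#' @param energy_scale soft per-atom energy scale (kcal/mol/atom):
#'   samples whose baseline-subtracted per-atom energy is far above the
#'   bulk of the data (steep-wall configurations) are down-weighted in
#'   the energy loss by the same rational scheme.
#' @param n_features random features per member per element.
#' @param lengthscale random-feature lengthscale in standardized
#'   descriptor units.
#' @param lambda relative ridge regularization.
#' @param bias_penalty multiplier on the ridge penalty of the per-member
#'   per-element bias columns; the shared composition baseline already
#'   calibrates self-atomic energies, so member biases are kept small to
#'   stop committee energy disagreement hiding in the force-null
#'   composition direction.
#' @param angular_penalty multiplier on the ridge penalty of the
#'   angular-descriptor linear columns: pair interactions dominate most
#'   reactive energetics, so three-body corrections are admitted only
#'   when the data demand them.
#' @param cos_penalty multiplier on the ridge penalty of the random
#'   Fourier columns relative to the linear descriptor columns: the
#'   linear block is additive over neighbors and so generalizes across
#'   system sizes, while the nonlinear corrections are kept small unless
#'   the data demand them.
#' @param fit_baseline fit the shared self-atomic-energy baseline by
#'   least squares on composition (needed when the labeler's energies
#'   contain large per-atom offsets, as electronic-structure energies
#'   do). Set `FALSE` for labelers whose isolated-atom energy is zero:
#'   an lm baseline would otherwise absorb mean binding energy into
#'   composition terms and push a spurious constant into the pair
#'   channels near the descriptor cutoff.
#' @param stop_lr,anneal_factor,max_epochs iterative-training bookkeeping
#'   (see above); `stop_lr` defaults to 1e-5.
#' @return list of class `nr_train_config`.
#' @export
train_config <- function(energy_weight = 1.0, force_weight = 0.3,
                         force_scale = 100, energy_scale = 20,
                         n_features = 8L,
                         lengthscale = 2.0, lambda = 1e-6,
                         cos_penalty = 1e4, bias_penalty = 1e4,
                         angular_penalty = 1, fit_baseline = TRUE,
                         stop_lr = 1e-5,
                         anneal_factor = 0.5, max_epochs = 1L) {
  if (energy_weight < 0 || force_weight < 0 ||
      (energy_weight == 0 && force_weight == 0))
    stop("loss weights must be >= 0 and not both zero")
  if (stop_lr <= 0) stop("stop_lr must be > 0")
  structure(list(energy_weight = energy_weight, force_weight = force_weight,
                 force_scale = force_scale, energy_scale = energy_scale,
                 n_features = as.integer(n_features),
                 lengthscale = lengthscale, lambda = lambda,
                 cos_penalty = cos_penalty, bias_penalty = bias_penalty,
                 angular_penalty = angular_penalty,
                 fit_baseline = fit_baseline,
                 stop_lr = stop_lr, anneal_factor = anneal_factor,
                 max_epochs = as.integer(max_epochs)),
            class = "nr_train_config")
}

#' Query-by-committee selection thresholds
#'
#' The final active-learning thresholds on the normalized ensemble energy
#' standard deviation (kcal/mol per sqrt(atom)) and the force standard
#' deviation (kcal/mol/A): 1.85 and 6.92.
#'
#' @param energy_threshold kcal/mol N^(-1/2), `> 0`.
#' @param force_threshold kcal/mol/A, `> 0`.
#' @return list of class `nr_thresholds`.
#' @export
selection_thresholds <- function(energy_threshold = 1.85,
                                 force_threshold = 6.92) {
  if (energy_threshold <= 0 || force_threshold <= 0)
    stop("thresholds must be > 0")
  structure(list(energy = energy_threshold, force = force_threshold),
            class = "nr_thresholds")
}

#' Does an uncertainty pair exceed the thresholds?
#'
#' Strict inequality on either channel: exactly-at-threshold does not
#' select.
#'
#' @param eps uncertainty pair from [qbc_uncertainty()] (list or numeric
#'   with elements/names `energy`, `force`).
#' @param thresholds an [selection_thresholds()].
#' @return logical.
#' @export
exceeds_thresholds <- function(eps, thresholds = selection_thresholds()) {
  e <- if (is.list(eps)) eps$energy else eps[["energy"]]
  f <- if (is.list(eps)) eps$force else eps[["force"]]
  (e > thresholds$energy) || (f > thresholds$force)
}

# ---------------------------------------------------------------------------
# internal feature machinery

# Basis for M stacked members: per element, each member's feature block is
# the D standardized descriptor channels taken linearly (the radial block
# is itself an RBF expansion of the pair distribution, so linear terms
# carry most of a near-pairwise PES) followed by n_features random Fourier
# features for nonlinear corrections. W ((M*(D+F)) x D) and b (M*(D+F))
# are expressed in raw descriptor coordinates via the scaler; is_cos marks
# the cosine rows.
make_basis <- function(desc_params, M, n_features, lengthscale, scaler) {
  D <- desc_params$length
  ne <- length(desc_params$elements)
  Fm <- D + n_features
  W <- vector("list", ne); b <- vector("list", ne)
  # channels essentially constant over the training data carry no signal;
  # excluding them (rather than rescaling by a tiny sd) keeps the model
  # bounded when unseen systems activate them
  active <- scaler$sd > 1e-4
  sd_safe <- ifelse(active, pmax(scaler$sd, 1e-4), 1)
  lin_scale <- ifelse(active, 1 / sd_safe, 0)
  Wlin <- diag(lin_scale, D)
  blin <- -scaler$mu * lin_scale
  for (e in seq_len(ne)) {
    We <- matrix(0, M * Fm, D); be <- numeric(M * Fm)
    for (m in seq_len(M)) {
      rows_lin <- (m - 1L) * Fm + seq_len(D)
      rows_cos <- (m - 1L) * Fm + D + seq_len(n_features)
      We[rows_lin, ] <- Wlin
      be[rows_lin] <- blin
      Wr <- matrix(stats::rnorm(n_features * D, sd = 1 / lengthscale),
                   n_features, D)
      br <- stats::runif(n_features, 0, 2 * pi)
      Wc <- sweep(Wr, 2, sd_safe, "/")
      Wc[, !active] <- 0
      We[rows_cos, ] <- Wc
      be[rows_cos] <- br - as.numeric(Wc %*% scaler$mu)
    }
    W[[e]] <- We; b[[e]] <- be
  }
  is_cos <- rep(rep(c(FALSE, TRUE), times = c(D, n_features)), M)
  list(W = W, b = b, M = M, F = Fm, is_cos = is_cos)
}

# Energy/force features for all stacked members on one configuration.
# Returns counts (ne), Zsum[[e]] ((M*F)), Ff[[e]] ((3N) x (M*F)) where
# Ff %*% w gives the force contribution (already negated gradient).
stacked_features <- function(basis, desc, need_forces = TRUE) {
  params <- desc$params
  ne <- length(params$elements)
  MF <- basis$M * basis$F
  N <- nrow(desc$X)
  elem_idx <- desc$elem_idx
  counts <- tabulate(elem_idx, nbins = ne)
  Z <- matrix(0, N, MF); S <- matrix(0, N, MF)
  Zsum <- vector("list", ne)
  for (e in seq_len(ne)) {
    rows <- which(elem_idx == e)
    Zsum[[e]] <- numeric(MF)
    if (!length(rows)) next
    arg <- desc$X[rows, , drop = FALSE] %*% t(basis$W[[e]])
    arg <- sweep(arg, 2, basis$b[[e]], "+")
    ic <- basis$is_cos
    Zr <- arg; Sr <- matrix(1, nrow(arg), ncol(arg))
    Zr[, ic] <- cos(arg[, ic, drop = FALSE])
    Sr[, ic] <- -sin(arg[, ic, drop = FALSE])
    Z[rows, ] <- Zr
    S[rows, ] <- Sr
    Zsum[[e]] <- colSums(Z[rows, , drop = FALSE])
  }
  out <- list(counts = counts, Zsum = Zsum, Ff = NULL)
  if (!need_forces) return(out)
  Ff <- lapply(seq_len(ne), function(e) matrix(0, 3L * N, MF))
  S_shells <- length(params$radial_centers)

  pr <- desc$pairs
  if (!is.null(pr) && length(pr$i)) {
    ce <- elem_idx[pr$i]          # center element (selects W and w-block)
    je <- pr$jcol_base            # neighbor-element column base
    for (e in seq_len(ne)) {
      for (jb in unique(je[ce == e])) {
        sel <- which(ce == e & je == jb)
        cols <- jb + seq_len(S_shells)
        tmat <- pr$dG[sel, , drop = FALSE] %*%
          t(basis$W[[e]][, cols, drop = FALSE])      # P x MF
        coeff <- tmat * S[pr$i[sel], , drop = FALSE]
        u <- cbind(pr$ux[sel], pr$uy[sel], pr$uz[sel])
        # d(feature)/dr_j = +coeff*u ; d/dr_i = -coeff*u ; Ff = -gradient
        vals3 <- cbind(coeff * u[, 1], coeff * u[, 2], coeff * u[, 3])
        accj <- rowsum(vals3, pr$j[sel])
        rj <- (as.integer(rownames(accj)) - 1L) * 3L
        acci <- rowsum(vals3, pr$i[sel])
        ri <- (as.integer(rownames(acci)) - 1L) * 3L
        for (cc in 1:3) {
          blk <- (cc - 1L) * MF + seq_len(MF)
          Ff[[e]][rj + cc, ] <- Ff[[e]][rj + cc, ] - accj[, blk]
          Ff[[e]][ri + cc, ] <- Ff[[e]][ri + cc, ] + acci[, blk]
        }
      }
    }
  }

  tr <- desc$triples
  if (!is.null(tr) && length(tr$i)) {
    ce <- elem_idx[tr$i]
    Q <- tr$Q
    fcp <- tr$fc1 * tr$fc2
    th_common <- tr$dG_th * (fcp * tr$dth_dc)      # T x Q (theta channel)
    r1_common <- 0.5 * tr$dG_r * fcp + tr$G * (tr$dfc1 * tr$fc2)
    r2_common <- 0.5 * tr$dG_r * fcp + tr$G * (tr$fc1 * tr$dfc2)
    inv12 <- 1 / (tr$r1 * tr$r2)
    u1 <- tr$v1 / tr$r1; u2 <- tr$v2 / tr$r2
    dc_dv1 <- tr$v2 * inv12 - tr$v1 * (tr$cth / tr$r1^2)
    dc_dv2 <- tr$v1 * inv12 - tr$v2 * (tr$cth / tr$r2^2)
    for (e in seq_len(ne)) {
      for (cb in unique(tr$colbase[ce == e])) {
        sel <- which(ce == e & tr$colbase == cb)
        cols <- cb + seq_len(Q)
        Wb <- t(basis$W[[e]][, cols, drop = FALSE])  # Q x MF
        Sc <- S[tr$i[sel], , drop = FALSE]
        Avec <- (th_common[sel, , drop = FALSE] %*% Wb) * Sc
        B1 <- (r1_common[sel, , drop = FALSE] %*% Wb) * Sc
        B2 <- (r2_common[sel, , drop = FALSE] %*% Wb) * Sc
        gj3 <- cbind(Avec * dc_dv1[sel, 1] + B1 * u1[sel, 1],
                     Avec * dc_dv1[sel, 2] + B1 * u1[sel, 2],
                     Avec * dc_dv1[sel, 3] + B1 * u1[sel, 3])
        gk3 <- cbind(Avec * dc_dv2[sel, 1] + B2 * u2[sel, 1],
                     Avec * dc_dv2[sel, 2] + B2 * u2[sel, 2],
                     Avec * dc_dv2[sel, 3] + B2 * u2[sel, 3])
        gi3 <- -(gj3 + gk3)
        accj <- rowsum(gj3, tr$j[sel])
        rj <- (as.integer(rownames(accj)) - 1L) * 3L
        acck <- rowsum(gk3, tr$k[sel])
        rk <- (as.integer(rownames(acck)) - 1L) * 3L
        acci <- rowsum(gi3, tr$i[sel])
        ri <- (as.integer(rownames(acci)) - 1L) * 3L
        for (cc in 1:3) {
          blk <- (cc - 1L) * MF + seq_len(MF)
          Ff[[e]][rj + cc, ] <- Ff[[e]][rj + cc, ] - accj[, blk]
          Ff[[e]][rk + cc, ] <- Ff[[e]][rk + cc, ] - acck[, blk]
          Ff[[e]][ri + cc, ] <- Ff[[e]][ri + cc, ] - acci[, blk]
        }
      }
    }
  }
  out$Ff <- Ff
  out
}

# Extract member m's design blocks from stacked features.
# Returns list(e_row (C1), Ff (3N x C1)) with layout
# [biases (ne) | w_e1 (F) | ... | w_ene (F)].
member_design <- function(feat, m, F, ne, need_forces = TRUE) {
  block <- (m - 1L) * F + seq_len(F)
  e_row <- c(feat$counts,
             unlist(lapply(seq_len(ne), function(e) feat$Zsum[[e]][block])))
  Ffm <- NULL
  if (need_forces && !is.null(feat$Ff)) {
    n3 <- nrow(feat$Ff[[1]])
    Ffm <- matrix(0, n3, ne + ne * F)
    for (e in seq_len(ne)) {
      Ffm[, ne + (e - 1L) * F + seq_len(F)] <- feat$Ff[[e]][, block]
    }
  }
  list(e_row = e_row, Ff = Ffm)
}

# ---------------------------------------------------------------------------

#' Train a query-by-committee ensemble
#'
#' Partitions the dataset into `2 * n_members` blocks (default 16) and
#' trains `n_members` members (default 8), each on all blocks except a
#' distinct validation and test block (the 14/1/1 scheme at the default
#' sizes). Each member has its own random-feature draw; coefficients are
#' solved in closed form from the weighted energy+force loss.
#'
#' @param dataset list of [labeled_sample()] objects (an `nr_dataset` or a
#'   bare list).
#' @param desc_params an [descriptor_params()] covering all elements in
#'   the dataset.
#' @param config an [train_config()].
#' @param n_members ensemble size M (`>= 2`).
#' @return object of class `nr_ensemble`.
#' @export
train_ensemble <- function(dataset, desc_params = descriptor_params(),
                           config = train_config(), n_members = 8L) {
  samples <- if (inherits(dataset, "nr_dataset")) dataset$samples else dataset
  ns <- length(samples)
  if (ns < 1L) stop("dataset is empty")
  n_blocks <- 2L * n_members
  if (ns < n_blocks)
    stop("dataset too small for the ", n_blocks, "-block split (", ns,
         " samples); reduce n_members")
  if (n_members < 2L) stop("n_members must be >= 2")
  ne <- length(desc_params$elements)

  # descriptor cache and scaler over all atoms of all samples
  descs <- lapply(samples, function(s)
    descriptor_set(s$config, desc_params, gradients = config$force_weight > 0))
  Xall <- do.call(rbind, lapply(descs, function(d) d$X))
  scaler <- list(mu = colMeans(Xall), sd = apply(Xall, 2, stats::sd))

  # shared self-atomic-energy baseline: least-squares fit of total energy
  # on element counts over the full dataset, removed before member fits so
  # that committee disagreement reflects environment effects, not
  # composition calibration
  cnt_mat <- t(vapply(samples, function(s)
    tabulate(match(s$config$species, desc_params$elements), ne),
    numeric(ne)))
  evec <- vapply(samples, function(s) s$energy, numeric(1))
  baseline <- if (isTRUE(config$fit_baseline)) {
    tryCatch(as.numeric(stats::lm.fit(cnt_mat, evec)$coefficients),
             error = function(e) rep(0, ne))
  } else rep(0, ne)
  baseline[!is.finite(baseline)] <- 0

  basis <- make_basis(desc_params, n_members, config$n_features,
                      config$lengthscale, scaler)
  Fm <- basis$F                       # per-member features (linear + cos)

  # block assignment: shuffled contiguous blocks
  perm <- sample.int(ns)
  block_of <- integer(ns)
  block_of[perm] <- rep(seq_len(n_blocks), length.out = ns)
  val_block <- 2L * seq_len(n_members) - 1L
  test_block <- 2L * seq_len(n_members)

  C1 <- ne + ne * Fm
  AtA <- replicate(n_members, matrix(0, C1, C1), simplify = FALSE)
  Aty <- replicate(n_members, numeric(C1), simplify = FALSE)
  feats <- vector("list", ns)
  need_f <- config$force_weight > 0
  for (s in seq_len(ns)) {
    feat <- stacked_features(basis, descs[[s]], need_forces = need_f)
    feats[[s]] <- feat
    Ns <- n_atoms(samples[[s]]$config)
    for (m in seq_len(n_members)) {
      if (block_of[s] %in% c(val_block[m], test_block[m])) next
      des <- member_design(feat, m, Fm, ne, need_f)
      e_res <- samples[[s]]$energy - sum(cnt_mat[s, ] * baseline)
      rob_e <- 1 / (1 + (e_res / (Ns * config$energy_scale))^2)
      we <- sqrt(config$energy_weight * rob_e) / Ns
      a_e <- des$e_row * we
      AtA[[m]] <- AtA[[m]] + tcrossprod(a_e)
      Aty[[m]] <- Aty[[m]] + a_e * (e_res * we)
      if (need_f) {
        yf <- as.numeric(t(samples[[s]]$forces))
        wf <- sqrt(config$force_weight /
                     (1 + (yf / config$force_scale)^2))
        Af <- des$Ff * wf
        AtA[[m]] <- AtA[[m]] + crossprod(Af)
        Aty[[m]] <- Aty[[m]] + as.numeric(crossprod(Af, yf * wf))
      }
    }
  }

  members <- vector("list", n_members)
  # cache energy design rows for the post-fit calibration below
  e_rows <- lapply(seq_len(ns), function(s) NULL)
  # per-column penalties: bias and linear descriptor columns at lambda,
  # cos columns at lambda * cos_penalty
  col_is_cos <- c(rep(FALSE, ne),
                  rep(basis$is_cos[seq_len(Fm)], ne))
  col_is_bias <- c(rep(TRUE, ne), rep(FALSE, ne * Fm))
  # linear columns follow the descriptor layout: radial block first,
  # angular block after n_radial
  feat_dim <- c(seq_len(desc_params$length), rep(NA_integer_,
                Fm - desc_params$length))
  col_dim <- c(rep(NA_integer_, ne), rep(feat_dim, ne))
  col_is_ang <- !is.na(col_dim) & col_dim > desc_params$n_radial
  cp <- if (is.null(config$cos_penalty)) 1 else config$cos_penalty
  bp <- if (is.null(config$bias_penalty)) 1 else config$bias_penalty
  ap <- if (is.null(config$angular_penalty)) 1 else config$angular_penalty
  for (m in seq_len(n_members)) {
    lam <- config$lambda * mean(diag(AtA[[m]]))
    lam_vec <- lam * ifelse(col_is_cos, cp,
                            ifelse(col_is_bias, bp,
                                   ifelse(col_is_ang, ap, 1)))
    theta <- solve(AtA[[m]] + diag(lam_vec, C1), Aty[[m]])
    # pin each member's per-element energy calibration on the full
    # dataset (the analogue of shared self-atomic energies): committee
    # energy disagreement should reflect geometry, not the composition
    # calibration drift of a weakly-constrained fit
    resid <- vapply(seq_len(ns), function(s) {
      des <- member_design(feats[[s]], m, Fm, ne, FALSE)
      samples[[s]]$energy - sum(cnt_mat[s, ] * baseline) -
        sum(des$e_row * theta)
    }, numeric(1))
    corr <- tryCatch(
      as.numeric(stats::lm.fit(cnt_mat, resid)$coefficients),
      error = function(e) rep(0, ne))
    corr[!is.finite(corr)] <- 0
    member_baseline <- baseline + corr
    block <- (m - 1L) * Fm + seq_len(Fm)
    members[[m]] <- structure(list(
      W = lapply(basis$W, function(w) w[block, , drop = FALSE]),
      b = lapply(basis$b, function(b) b[block]),
      is_cos = basis$is_cos[seq_len(Fm)],
      theta = as.numeric(theta),
      baseline = member_baseline,
      n_features = Fm,
      desc_params = desc_params,
      index = m
    ), class = "nr_member")
  }

  # held-out metrics
  metrics <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    for (split in c("validation", "test")) {
      blk <- if (split == "validation") val_block[m] else test_block[m]
      idx <- which(block_of == blk)
      eres <- numeric(0); fres <- numeric(0)
      for (s in idx) {
        des <- member_design(feats[[s]], m, Fm, ne, need_f)
        Ns <- n_atoms(samples[[s]]$config)
        epred <- sum(des$e_row * members[[m]]$theta) +
          sum(cnt_mat[s, ] * members[[m]]$baseline)
        eres <- c(eres, (epred - samples[[s]]$energy) / Ns)
        if (need_f) {
          fpred <- as.numeric(des$Ff %*% members[[m]]$theta)
          fres <- c(fres, fpred - as.numeric(t(samples[[s]]$forces)))
        }
      }
      metrics[[m]][[split]] <- list(
        rmse_energy_per_atom = if (length(eres)) sqrt(mean(eres^2)) else NA_real_,
        rmse_force = if (length(fres)) sqrt(mean(fres^2)) else NA_real_,
        n = length(idx))
    }
  }

  structure(list(members = members, n_members = n_members,
                 desc_params = desc_params, train_config = config,
                 basis = basis, scaler = scaler, baseline = baseline,
                 n_samples = ns,
                 block_of = block_of, metrics = metrics,
                 converged = TRUE, final_lr = config$stop_lr / 2),
            class = "nr_ensemble")
}

#' @export
print.nr_ensemble <- function(x, ...) {
  cat(sprintf("<nr_ensemble> %d members, trained on %d samples, %d features\n",
              x$n_members, x$n_samples, x$train_config$n_features))
  invisible(x)
}

#' Member-resolved ensemble prediction
#'
#' @param ensemble an [train_ensemble()] result.
#' @param config an [configuration()].
#' @param forces compute member forces too.
#' @return list with `energies` (length M), `forces` (list of N x 3
#'   matrices or NULL), `mean_energy`, `mean_forces`.
#' @export
ensemble_predict <- function(ensemble, config, forces = TRUE) {
  desc <- descriptor_set(config, ensemble$desc_params, gradients = forces)
  ne <- length(ensemble$desc_params$elements)
  M <- ensemble$n_members
  basis <- ensemble$basis
  if (is.null(basis)) {
    basis <- list(
      W = lapply(seq_len(ne), function(e)
        do.call(rbind, lapply(ensemble$members, function(mb) mb$W[[e]]))),
      b = lapply(seq_len(ne), function(e)
        unlist(lapply(ensemble$members, function(mb) mb$b[[e]]))),
      M = M, F = ensemble$members[[1]]$n_features,
      is_cos = rep(ensemble$members[[1]]$is_cos, M))
  }
  Fn <- basis$F
  feat <- stacked_features(basis, desc, need_forces = forces)
  N <- n_atoms(config)
  energies <- numeric(M)
  flist <- if (forces) vector("list", M) else NULL
  for (m in seq_len(M)) {
    des <- member_design(feat, m, Fn, ne, forces)
    mb <- ensemble$members[[m]]$baseline
    base_e <- if (is.null(mb)) 0 else sum(feat$counts * mb)
    energies[m] <- sum(des$e_row * ensemble$members[[m]]$theta) + base_e
    if (forces) {
      fv <- as.numeric(des$Ff %*% ensemble$members[[m]]$theta)
      flist[[m]] <- matrix(fv, N, 3, byrow = TRUE)
    }
  }
  mean_forces <- NULL
  if (forces) {
    mean_forces <- Reduce(`+`, flist) / M
  }
  list(energies = energies, forces = flist,
       mean_energy = mean(energies), mean_forces = mean_forces)
}

#' Predict energy and forces with one ensemble member
#'
#' The total energy is the sum of per-atom energies; forces are the exact
#' negative gradient of the member energy.
#'
#' @param member an `nr_member` (element of `ensemble$members`).
#' @param config an [configuration()].
#' @return list with `energy` and `forces` (N x 3).
#' @export
predict_member <- function(member, config) {
  bad <- setdiff(unique(config$species), member$desc_params$elements)
  if (length(bad))
    stop("member does not support element(s): ", paste(bad, collapse = ", "))
  desc <- descriptor_set(config, member$desc_params, gradients = TRUE)
  ne <- length(member$desc_params$elements)
  basis <- list(W = member$W, b = member$b, M = 1L, F = member$n_features,
                is_cos = member$is_cos)
  feat <- stacked_features(basis, desc, need_forces = TRUE)
  des <- member_design(feat, 1L, member$n_features, ne, TRUE)
  N <- n_atoms(config)
  base_e <- if (is.null(member$baseline)) 0 else
    sum(feat$counts * member$baseline)
  list(energy = sum(des$e_row * member$theta) + base_e,
       forces = matrix(as.numeric(des$Ff %*% member$theta), N, 3,
                       byrow = TRUE))
}

#' Query-by-committee uncertainty
#'
#' The normalized ensemble disagreement: `energy` is the population
#' standard deviation of member total energies divided by `sqrt(N)`
#' (kcal/mol per sqrt(atom)); `force` aggregates, over atoms, the Euclidean
#' norm of the per-component population standard deviation of member
#' forces (kcal/mol/A) — by default the maximum over atoms
#' (`aggregate = "max"`), optionally the mean.
#'
#' @param ensemble an `nr_ensemble` (M >= 2).
#' @param config an [configuration()].
#' @param aggregate `"max"` (default) or `"mean"` over atoms.
#' @param prediction optional precomputed [ensemble_predict()] result.
#' @return list with `energy` and `force`.
#' @export
qbc_uncertainty <- function(ensemble, config, aggregate = c("max", "mean"),
                            prediction = NULL) {
  aggregate <- match.arg(aggregate)
  if (ensemble$n_members < 2L) stop("ensemble must have >= 2 members")
  pred <- if (is.null(prediction)) ensemble_predict(ensemble, config) else
    prediction
  M <- length(pred$energies)
  N <- n_atoms(config)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  eps_e <- pop_sd(pred$energies) / sqrt(N)
  farr <- simplify2array(pred$forces)        # N x 3 x M
  fmean <- apply(farr, c(1, 2), mean)
  fvar <- apply(sweep(farr, c(1, 2), fmean)^2, c(1, 2), mean)
  per_atom <- sqrt(rowSums(fvar))
  eps_f <- if (aggregate == "max") max(per_atom) else mean(per_atom)
  list(energy = eps_e, force = eps_f)
}

#' Use an ensemble as an MD calculator
#'
#' Wraps mean member energy/forces as an `nr_calculator`.
#'
#' @param ensemble an `nr_ensemble`.
#' @return an `nr_calculator`.
#' @export
as_calculator <- function(ensemble) {
  stopifnot(inherits(ensemble, "nr_ensemble"))
  ev <- function(config) {
    pred <- ensemble_predict(ensemble, config)
    list(energy = pred$mean_energy, forces = pred$mean_forces)
  }
  calculator(ev, elements = ensemble$desc_params$elements,
             cutoff = ensemble$desc_params$radial_cutoff,
             label = "ensemble")
}
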