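#' Active-learning campaign configuration
#'
#' Desk-scale defaults, scaled down from the full workflow (100 bootstrap
#' cells, up to 1 ns per sampling run, 50 ps mean-simulation-time
#' convergence): 10 bootstrap cells, 8 nanoreactor simulations per
#' generation, 10 ps per simulation and a 5 ps convergence target.
#'
#' @param bootstrap_cells number of labeled bootstrap cells.
#' @param sims_per_generation nanoreactor simulations per generation.
#' @param t_max_fs maximum simulated time per nanoreactor run (fs).
#' @param convergence_target_fs campaign converges when the mean
#'   simulation time over a generation reaches this (fs).
#' @param builder policy for random starting systems
#'   ([builder_policy()]).
#' @param schedule_policy policy for random schedules
#'   ([schedule_policy()]); its `t_max` is overridden by `t_max_fs`.
#' @param thresholds final [selection_thresholds()].
#' @param threshold_ramp_generations generations over which thresholds
#'   ramp linearly from 50% to 100% of their final values (exploitation
#'   early, exploration late).
#' @param md an [md_params()].
#' @param train an [train_config()].
#' @param n_members ensemble size.
#' @param desc_params an [descriptor_params()]; defaults to one covering
#'   the policy's elements.
#' @param randomize_monitor draw the monitor interval uniformly from
#'   5-50 steps per simulation instead of using `md$monitor_interval`.
#' @param match_density_start start each drawn density schedule at the
#'   as-built density of the starting box (no discontinuous rescale at
#'   t = 0); the drawn `rho_start` is overridden.
#' @param relax_bootstrap relax bootstrap cells on the labeler surface
#'   before labeling (packed boxes use idealized gas-phase geometries
#'   that are not the labeler's equilibrium).
#' @param relax_starts relax each fresh sampling box to the labeler's
#'   minimum-energy structure before running the nanoreactor (the
#'   case-study protocols likewise minimize initial structures before
#'   dynamics).
#' @param max_label_force labeled samples whose max force component
#'   exceeds this (kcal/mol/A, default 3000) are discarded as failed labels, mirroring
#'   how non-converged reference calculations are dropped.
#' @return list of class `nr_al_config`.
#' @export
al_config <- function(bootstrap_cells = 10L, sims_per_generation = 8L,
                      t_max_fs = 10000, convergence_target_fs = 5000,
                      builder = builder_policy(),
                      schedule_policy = nanoreactr::schedule_policy(),
                      thresholds = selection_thresholds(),
                      threshold_ramp_generations = 5L,
                      md = md_params(), train = train_config(),
                      n_members = 8L, desc_params = NULL,
                      randomize_monitor = FALSE,
                      match_density_start = TRUE,
                      relax_bootstrap = TRUE, relax_starts = TRUE,
                      max_label_force = 3000) {
  stopifnot(bootstrap_cells >= 1L, sims_per_generation >= 1L,
            t_max_fs > 0, convergence_target_fs > 0)
  schedule_policy$t_max <- t_max_fs
  if (is.null(desc_params)) {
    elems <- sort(unique(unlist(lapply(builder$molecules, function(nm)
      seed_molecule(nm)$species))))
    desc_params <- descriptor_params(elements = elems)
  }
  structure(list(bootstrap_cells = as.integer(bootstrap_cells),
                 sims_per_generation = as.integer(sims_per_generation),
                 t_max_fs = t_max_fs,
                 convergence_target_fs = convergence_target_fs,
                 builder = builder, schedule_policy = schedule_policy,
                 thresholds = thresholds,
                 threshold_ramp_generations =
                   as.integer(threshold_ramp_generations),
                 md = md, train = train, n_members = as.integer(n_members),
                 desc_params = desc_params,
                 randomize_monitor = randomize_monitor,
                 match_density_start = match_density_start,
                 relax_bootstrap = relax_bootstrap,
                 relax_starts = relax_starts,
                 max_label_force = max_label_force),
            class = "nr_al_config")
}

#' Generation-dependent selection thresholds
#'
#' Linear ramp from 50% to 100% of the final threshold values over
#' `ramp` generations (later generations tolerate more disagreement
#' before selecting).
#'
#' @param generation 1-based generation index.
#' @param final final [selection_thresholds()].
#' @param ramp ramp length in generations.
#' @return an `nr_thresholds`.
#' @export
generation_thresholds <- function(generation, final = selection_thresholds(),
                                  ramp = 5L) {
  f <- if (ramp <= 1L) 1 else
    min(1, 0.5 + 0.5 * (generation - 1) / (ramp - 1))
  selection_thresholds(f * final$energy, f * final$force)
}

#' Bootstrap dataset of labeled random cells
#'
#' Builds `config$bootstrap_cells` random seed-molecule boxes under the
#' builder policy and labels each with the given calculator. Labeling
#' failures are skipped (and counted in the result's attributes).
#'
#' @param config an [al_config()].
#' @param labeler an `nr_calculator`.
#' @return an `nr_dataset`: list with `samples` and `provenance`.
#' @export
bootstrap_dataset <- function(config, labeler) {
  configs <- lapply(seq_len(config$bootstrap_cells), function(k)
    random_nr_system(config$builder))
  if (isTRUE(config$relax_bootstrap)) {
    configs <- lapply(configs, relax_configuration, calc = labeler,
                      fmax = 5, max_steps = 400L)
  }
  lab <- label_configurations(configs, labeler)
  lab$samples <- filter_label_forces(lab$samples, config$max_label_force)
  dataset <- structure(list(samples = lab$samples,
                            provenance = list(labeler = labeler$label,
                                              stage = "bootstrap")),
                       class = "nr_dataset")
  attr(dataset, "n_failed") <- length(lab$failed)
  dataset
}

#' @export
print.nr_dataset <- function(x, ...) {
  cat(sprintf("<nr_dataset> %d labeled samples\n", length(x$samples)))
  invisible(x)
}

#' Initial active-learning state
#'
#' @param dataset an `nr_dataset` (e.g. from [bootstrap_dataset()]).
#' @param config an [al_config()].
#' @return list of class `nr_al_state`.
#' @export
al_state <- function(dataset, config) {
  structure(list(dataset = dataset, generation = 0L, ensemble = NULL,
                 config = config,
                 history = tibble::tibble(
                   generation = integer(), n_simulations = integer(),
                   n_flagged = integer(), n_labeled = integer(),
                   mean_sim_time_fs = numeric(), dataset_size = integer())),
            class = "nr_al_state")
}

#' @export
print.nr_al_state <- function(x, ...) {
  cat(sprintf("<nr_al_state> generation %d, dataset %d samples\n",
              x$generation, length(x$dataset$samples)))
  if (nrow(x$history)) print(x$history)
  invisible(x)
}

#' Run one active-learning generation
#'
#' Trains the ensemble on the current dataset, runs the configured number
#' of nanoreactor simulations from freshly drawn systems and schedules,
#' labels every flagged configuration, and appends the new samples. The
#' history records the mean simulation time (flagged runs count their
#' flag time, unflagged runs the full `t_max`).
#'
#' @param state an `nr_al_state`.
#' @param labeler an `nr_calculator`.
#' @return the advanced `nr_al_state`.
#' @export
al_generation <- function(state, labeler) {
  cfg <- state$config
  gen <- state$generation + 1L
  ens <- train_ensemble(state$dataset, desc_params = cfg$desc_params,
                        config = cfg$train, n_members = cfg$n_members)
  thr <- generation_thresholds(gen, cfg$thresholds,
                               cfg$threshold_ramp_generations)
  flagged <- list(); sim_times <- numeric(0); flag_records <- list()
  for (s in seq_len(cfg$sims_per_generation)) {
    sys <- random_nr_system(cfg$builder)
    if (isTRUE(cfg$relax_starts)) {
      sys <- relax_configuration(sys, labeler, fmax = 5, max_steps = 400L)
    }
    sch <- draw_schedule(cfg$schedule_policy)
    if (isTRUE(cfg$match_density_start)) sch$density$start <- mass_density(sys)
    md <- cfg$md
    if (cfg$randomize_monitor) md$monitor_interval <- sample(5:50, 1L)
    res <- run_nanoreactor(sys, sch, ens, thresholds = thr, params = md,
                           t_max = cfg$t_max_fs, record = FALSE)
    sim_times <- c(sim_times, res$elapsed)
    if (!is.null(res$flagged)) {
      flagged[[length(flagged) + 1L]] <- res$flagged
      flag_records[[length(flag_records) + 1L]] <-
        list(time = res$flag_time, reason = res$reason,
             uncertainty = res$uncertainty, schedules = sch)
    }
  }
  n_labeled <- 0L
  if (length(flagged)) {
    lab <- label_configurations(flagged, labeler)
    lab$samples <- filter_label_forces(lab$samples, cfg$max_label_force)
    if (length(lab$samples)) {
      state$dataset$samples <- c(state$dataset$samples, lab$samples)
      n_labeled <- length(lab$samples)
    }
  }
  state$generation <- gen
  state$ensemble <- ens
  state$thresholds_used <- thr
  state$history <- dplyr::bind_rows(state$history, tibble::tibble(
    generation = gen, n_simulations = cfg$sims_per_generation,
    n_flagged = length(flagged), n_labeled = n_labeled,
    mean_sim_time_fs = mean(sim_times),
    dataset_size = length(state$dataset$samples)))
  state$flag_records <- c(state$flag_records, list(flag_records))
  state
}

#' Run the campaign until convergence
#'
#' Repeats [al_generation()] until the mean simulation time of a
#' generation reaches the configured target, or `max_generations` is hit.
#'
#' @param state an `nr_al_state`.
#' @param labeler an `nr_calculator`.
#' @param max_generations hard cap on generations (`>= 1`).
#' @return the final `nr_al_state` (with `converged` attribute).
#' @export
run_until_converged <- function(state, labeler, max_generations = 15L) {
  stopifnot(max_generations >= 1L)
  converged <- FALSE
  for (g in seq_len(max_generations)) {
    state <- al_generation(state, labeler)
    last <- state$history$mean_sim_time_fs[nrow(state$history)]
    if (last >= state$config$convergence_target_fs) {
      converged <- TRUE
      break
    }
  }
  attr(state, "converged") <- converged
  state
}

# quality filter on labeled samples: drop extreme-force labels
filter_label_forces <- function(samples, max_force) {
  if (is.null(max_force) || !is.finite(max_force)) return(samples)
  keep <- vapply(samples, function(s) max(abs(s$forces)) <= max_force,
                 logical(1))
  samples[keep]
}
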