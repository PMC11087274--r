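#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an active-learning state
#'
#' Returns the per-generation history table: simulations run, flags
#' raised, samples labeled, mean simulation time and dataset size.
#'
#' @param x an `nr_al_state`.
#' @param ... unused.
#' @return a tibble, one row per generation.
#' @export
tidy.nr_al_state <- function(x, ...) x$history

#' @rdname tidy.nr_al_state
#' @export
glance.nr_al_state <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    generations = x$generation,
    dataset_size = length(x$dataset$samples),
    total_flagged = sum(h$n_flagged),
    final_mean_sim_time_fs = if (nrow(h)) h$mean_sim_time_fs[nrow(h)]
      else NA_real_,
    converged = isTRUE(attr(x, "converged")))
}

#' Tidy an ensemble fit
#'
#' One row per member with held-out (validation/test) per-atom energy and
#' force RMSEs.
#'
#' @param x an `nr_ensemble`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nr_ensemble <- function(x, ...) {
  rows <- lapply(seq_len(x$n_members), function(m) {
    mm <- x$metrics[[m]]
    tibble::tibble(
      member = m,
      rmse_energy_val = mm$validation$rmse_energy_per_atom,
      rmse_force_val = mm$validation$rmse_force,
      rmse_energy_test = mm$test$rmse_energy_per_atom,
      rmse_force_test = mm$test$rmse_force)
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.nr_ensemble
#' @export
glance.nr_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_members = x$n_members,
    n_samples = x$n_samples,
    n_features = x$train_config$n_features,
    mean_rmse_energy_test = mean(td$rmse_energy_test, na.rm = TRUE),
    mean_rmse_force_test = mean(td$rmse_force_test, na.rm = TRUE),
    converged = isTRUE(x$converged))
}

#' Tidy a species census
#'
#' @param x an `nr_census`.
#' @param ... unused.
#' @return the long per-frame counts tibble.
#' @export
tidy.nr_census <- function(x, ...) x$counts

#' @rdname tidy.nr_census
#' @export
glance.nr_census <- function(x, ...) {
  tibble::tibble(n_species = nrow(x$species),
                 n_frames = if (nrow(x$counts)) max(x$counts$frame) else 0L,
                 key_version = x$key_version)
}

#' Plot per-frame thermodynamic scalars of a trajectory
#'
#' @param object an `nr_trajectory` with recorded scalars.
#' @param ... unused.
#' @return a ggplot object (time series faceted by scalar).
#' @export
autoplot.nr_trajectory <- function(object, ...) {
  if (is.null(object$scalars)) stop("trajectory has no recorded scalars")
  df <- cbind(data.frame(time = object$times), object$scalars)
  long <- stats::reshape(df, direction = "long",
                         varying = names(object$scalars),
                         v.names = "value",
                         times = names(object$scalars),
                         timevar = "scalar")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~scalar, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (fs)", y = NULL)
}

#' Plot species tracking series
#'
#' @param object an `nr_species_series` from [track_species()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nr_species_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$count,
                               color = .data$target)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (fs)", y = "molecule count", color = "species")
}

#' Plot an active-learning history
#'
#' Mean simulation time per generation (the convergence criterion) with
#' the dataset size as a secondary panel.
#'
#' @param object an `nr_al_state`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nr_al_state <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(generation = h$generation, value = h$mean_sim_time_fs,
               panel = "mean simulation time (fs)"),
    data.frame(generation = h$generation, value = h$dataset_size,
               panel = "dataset size"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL)
}
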