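NR_MODEL_VERSION <- 1L

#' Write / read a trained ensemble archive
#'
#' A self-contained JSON archive: descriptor parameters, member weights,
#' shared scaler and baseline, training metadata and a format version.
#' Reads refuse unknown versions, so archives from different releases are
#' never silently mixed.
#'
#' @param ensemble an `nr_ensemble`.
#' @param path file path (conventionally `.json`).
#' @return `path` invisibly (write); an `nr_ensemble` (read).
#' @export
write_ensemble <- function(ensemble, path) {
  dp <- ensemble$desc_params
  obj <- list(
    format = "nr_ensemble", version = NR_MODEL_VERSION,
    descriptor = list(
      elements = dp$elements, radial_cutoff = dp$radial_cutoff,
      angular_cutoff = dp$angular_cutoff, radial_centers = dp$radial_centers,
      radial_eta = dp$radial_eta,
      angular_sections = length(dp$theta_s),
      angular_centers = dp$angular_centers,
      angular_eta = dp$angular_eta, zeta = dp$zeta),
    train_config = unclass(ensemble$train_config),
    scaler = ensemble$scaler,
    baseline = ensemble$baseline,
    n_members = ensemble$n_members,
    n_samples = ensemble$n_samples,
    members = lapply(ensemble$members, function(mb) list(
      W = lapply(mb$W, as.numeric),
      W_dim = dim(mb$W[[1]]),
      b = mb$b, is_cos = mb$is_cos, theta = mb$theta,
      baseline = mb$baseline, n_features = mb$n_features))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  if (is.null(obj$version) || unlist(obj$version) != NR_MODEL_VERSION)
    stop("unsupported ensemble archive version: ",
         if (is.null(obj$version)) "<missing>" else unlist(obj$version))
  d <- obj$descriptor
  dp <- descriptor_params(
    elements = as.character(unlist(d$elements)),
    radial_cutoff = num(d$radial_cutoff),
    angular_cutoff = num(d$angular_cutoff),
    radial_centers = num(d$radial_centers),
    radial_eta = num(d$radial_eta),
    angular_sections = num(d$angular_sections),
    angular_centers = num(d$angular_centers),
    angular_eta = num(d$angular_eta), zeta = num(d$zeta))
  tc_raw <- lapply(obj$train_config, unlist)
  tc <- do.call(train_config,
                tc_raw[intersect(names(tc_raw), names(formals(train_config)))])
  n_members <- as.integer(unlist(obj$n_members))
  members <- lapply(seq_len(n_members), function(m) {
    mm <- obj$members[[m]]
    Wd <- as.integer(unlist(mm$W_dim))
    structure(list(
      W = lapply(mm$W, function(w) matrix(num(w), Wd[1], Wd[2])),
      b = lapply(mm$b, num),
      is_cos = as.logical(unlist(mm$is_cos)),
      theta = num(mm$theta),
      baseline = num(mm$baseline),
      n_features = as.integer(unlist(mm$n_features)),
      desc_params = dp, index = m), class = "nr_member")
  })
  structure(list(members = members, n_members = n_members,
                 desc_params = dp, train_config = tc,
                 basis = NULL,
                 scaler = list(mu = num(obj$scaler$mu),
                               sd = num(obj$scaler$sd)),
                 baseline = num(obj$baseline),
                 n_samples = as.integer(unlist(obj$n_samples)),
                 metrics = NULL, converged = TRUE),
            class = "nr_ensemble")
}
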