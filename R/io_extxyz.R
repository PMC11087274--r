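#' Read an extended-XYZ file
#'
#' Parses the standard extended-XYZ layout: per frame an atom count, a
#' comment line of `key=value` pairs (including `Lattice="ax ay az bx ..."`
#' and `Properties=species:S:1:pos:R:3[:forces:R:3]`), then one row per
#' atom. Orthorhombic lattices only. Recognized frame scalars (`energy`,
#' `time`, `temperature`, `density`) are carried into the trajectory;
#' forces, when present, are attached to each frame as the `forces`
#' attribute.
#'
#' @param path file path.
#' @param as_trajectory return an [trajectory()] even for a single frame.
#' @return an [configuration()] (single frame, default) or an
#'   [trajectory()].
#' @export
read_extxyz <- function(path, as_trajectory = NA) {
  parsed <- read_extxyz_frames(path)
  frames <- parsed$frames; times <- parsed$times; scalars <- parsed$scalars
  fidx <- length(frames)
  single <- fidx == 1L && (is.na(as_trajectory) || !as_trajectory)
  if (single) return(frames[[1L]])
  sc <- NULL
  keys <- c("temperature", "density", "energy")
  have <- keys[keys %in% unlist(lapply(scalars, names))]
  if (length(have)) {
    sc <- as.data.frame(lapply(have, function(k)
      vapply(scalars, function(s)
        if (is.null(s[[k]])) NA_real_ else as.numeric(s[[k]]), numeric(1))))
    names(sc) <- have
  }
  trajectory(frames, times, sc)
}

# frame-level reader shared by read_extxyz (which enforces the trajectory
# invariants) and read_dataset (whose samples may differ in composition)
read_extxyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); scalars <- list(); times <- numeric(0)
  ln <- 1L; fidx <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1L)
      stop("malformed atom count at line ", ln)
    if (ln + 1L + nat > length(lines) + 0L)
      stop("truncated frame ", fidx, " starting at line ", ln)
    header <- parse_extxyz_header(lines[ln + 1L], ln + 1L)
    body <- lines[(ln + 2L):(ln + 1L + nat)]
    toks <- strsplit(trimws(body), "[ \t]+")
    ncol_expect <- header$ncols
    badrow <- which(vapply(toks, length, integer(1)) < ncol_expect)
    if (length(badrow))
      stop("malformed atom row at line ", ln + 1L + badrow[1],
           " (frame ", fidx, ")")
    species <- vapply(toks, `[[`, character(1), header$species_col)
    pos <- t(vapply(toks, function(tk)
      as.numeric(tk[header$pos_cols]), numeric(3)))
    if (!all(is.finite(pos)))
      stop("non-numeric coordinates in frame ", fidx)
    cfg <- configuration(species, pos, header$cell, wrap = FALSE)
    if (!is.null(header$force_cols)) {
      fr <- t(vapply(toks, function(tk)
        as.numeric(tk[header$force_cols]), numeric(3)))
      attr(cfg, "forces") <- fr
      attr(cfg, "forces_units") <- "kcal/mol/A"
    }
    if (!is.null(header$info$energy))
      attr(cfg, "energy") <- as.numeric(header$info$energy)
    frames[[fidx]] <- cfg
    times <- c(times, if (!is.null(header$info$time))
      as.numeric(header$info$time) else fidx - 1)
    scalars[[fidx]] <- header$info
    ln <- ln + 2L + nat
  }
  if (fidx == 0L) stop("no frames found in ", path)
  list(frames = frames, times = times, scalars = scalars)
}

parse_extxyz_header <- function(line, lineno) {
  # tokenize key=value with possible double-quoted values
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^ \t]+)'
  m <- gregexpr(pat, line, perl = TRUE)
  if (m[[1]][1] == -1) stop("malformed extended-XYZ header at line ", lineno)
  toks <- regmatches(line, m)[[1]]
  kv <- list()
  for (tk in toks) {
    eq <- regexpr("=", tk, fixed = TRUE)
    key <- substr(tk, 1, eq - 1)
    val <- substr(tk, eq + 1, nchar(tk))
    val <- gsub('^"|"$', "", val)
    kv[[key]] <- val
  }
  lat_key <- names(kv)[tolower(names(kv)) == "lattice"]
  if (!length(lat_key))
    stop("missing Lattice in extended-XYZ header at line ", lineno)
  lat <- as.numeric(strsplit(trimws(kv[[lat_key[1]]]), "[ \t]+")[[1]])
  if (length(lat) != 9 || anyNA(lat))
    stop("malformed Lattice at line ", lineno)
  Lm <- matrix(lat, 3, 3, byrow = TRUE)
  if (any(abs(Lm[upper.tri(Lm) | lower.tri(Lm)]) > 1e-10))
    stop("only orthorhombic lattices are supported (line ", lineno, ")")
  pbc <- c(TRUE, TRUE, TRUE)
  pbc_key <- names(kv)[tolower(names(kv)) == "pbc"]
  if (length(pbc_key)) {
    pv <- toupper(strsplit(trimws(kv[[pbc_key[1]]]), "[ \t]+")[[1]])
    pbc <- rep_len(pv %in% c("T", "TRUE", "1"), 3L)
  }
  prop_key <- names(kv)[tolower(names(kv)) == "properties"]
  props <- if (length(prop_key)) kv[[prop_key[1]]] else "species:S:1:pos:R:3"
  ptoks <- strsplit(props, ":")[[1]]
  if (length(ptoks) %% 3 != 0)
    stop("malformed Properties at line ", lineno)
  col <- 1L; species_col <- NA_integer_; pos_cols <- NULL; force_cols <- NULL
  for (k in seq(1, length(ptoks), by = 3)) {
    nm <- ptoks[k]; width <- as.integer(ptoks[k + 2])
    if (nm == "species") species_col <- col
    if (nm == "pos") pos_cols <- col:(col + 2L)
    if (nm %in% c("forces", "force")) force_cols <- col:(col + 2L)
    col <- col + width
  }
  if (is.na(species_col) || is.null(pos_cols))
    stop("Properties must include species and pos (line ", lineno, ")")
  info <- kv[!tolower(names(kv)) %in%
               c("lattice", "properties", "pbc")]
  list(cell = cell(diag(Lm), periodic = pbc), species_col = species_col,
       pos_cols = pos_cols, force_cols = force_cols, ncols = col - 1L,
       info = info)
}

#' Write configurations or trajectories as extended-XYZ
#'
#' @param x an [configuration()], [trajectory()] or [labeled_sample()].
#' @param path output file path.
#' @param forces optional N x 3 matrix (single configuration) to embed.
#' @param energy optional scalar energy to embed.
#' @param append append to an existing file.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(x, path, forces = NULL, energy = NULL,
                         append = FALSE) {
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  emit <- function(cfg, info = list(), forces = NULL) {
    N <- n_atoms(cfg)
    L <- cfg$cell$edge_lengths
    lat <- sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g"',
                   L[1], L[2], L[3])
    props <- if (is.null(forces)) "Properties=species:S:1:pos:R:3" else
      "Properties=species:S:1:pos:R:3:forces:R:3"
    pbc <- sprintf('pbc="%s"', paste(ifelse(cfg$cell$periodic, "T", "F"),
                                     collapse = " "))
    extra <- if (length(info))
      paste(vapply(names(info), function(k)
        sprintf("%s=%.12g", k, as.numeric(info[[k]])), character(1)),
        collapse = " ")
    else ""
    writeLines(as.character(N), con)
    writeLines(trimws(paste(lat, props, pbc, extra)), con)
    for (i in seq_len(N)) {
      row <- sprintf("%-2s %18.10f %18.10f %18.10f", cfg$species[i],
                     cfg$positions[i, 1], cfg$positions[i, 2],
                     cfg$positions[i, 3])
      if (!is.null(forces)) {
        row <- paste0(row, sprintf(" %18.10f %18.10f %18.10f",
                                   forces[i, 1], forces[i, 2], forces[i, 3]))
      }
      writeLines(row, con)
    }
  }
  if (inherits(x, "nr_config")) {
    info <- list()
    if (!is.null(energy)) info$energy <- energy
    else if (!is.null(attr(x, "energy"))) info$energy <- attr(x, "energy")
    if (is.null(forces)) forces <- attr(x, "forces")
    emit(x, info, forces)
  } else if (inherits(x, "nr_sample")) {
    emit(x$config, list(energy = x$energy), x$forces)
  } else if (inherits(x, "nr_trajectory")) {
    for (f in seq_along(x$frames)) {
      info <- list(time = x$times[f])
      if (!is.null(x$scalars)) {
        for (k in names(x$scalars)) {
          v <- x$scalars[f, k]
          if (is.finite(v)) info[[k]] <- v
        }
      }
      emit(x$frames[[f]], info, attr(x$frames[[f]], "forces"))
    }
  } else stop("cannot write object of class ", class(x)[1])
  invisible(path)
}

# ---------------------------------------------------------------------------

NR_DATASET_VERSION <- 1L

#' Write / read a labeled dataset archive
#'
#' A dataset archive is a multi-frame extended-XYZ file (energies and
#' forces embedded per frame) plus a JSON sidecar (`<path>.json`) holding
#' the format version and provenance. Reads refuse unknown versions.
#'
#' @param dataset an `nr_dataset` or list of [labeled_sample()]s.
#' @param path archive path (the `.json` sidecar sits next to it).
#' @param provenance named list merged into the sidecar.
#' @return `path` invisibly (write); an `nr_dataset` (read).
#' @export
write_dataset <- function(dataset, path, provenance = list()) {
  samples <- if (inherits(dataset, "nr_dataset")) dataset$samples else dataset
  if (file.exists(path)) file.remove(path)
  for (s in samples) write_extxyz(s, path, append = TRUE)
  prov <- utils::modifyList(
    if (inherits(dataset, "nr_dataset") && !is.null(dataset$provenance))
      dataset$provenance else list(),
    provenance)
  meta <- list(format = "nr_dataset", version = NR_DATASET_VERSION,
               n_samples = length(samples), provenance = prov)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing dataset sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$version) || meta$version != NR_DATASET_VERSION)
    stop("unsupported dataset archive version: ",
         if (is.null(meta$version)) "<missing>" else meta$version)
  parsed <- read_extxyz_frames(path)
  samples <- lapply(seq_along(parsed$frames), function(f) {
    cfg <- parsed$frames[[f]]
    fr <- attr(cfg, "forces")
    en <- attr(cfg, "energy")
    if (is.null(en) && !is.null(parsed$scalars[[f]]$energy))
      en <- as.numeric(parsed$scalars[[f]]$energy)
    if (is.null(fr) || is.null(en) || !is.finite(en))
      stop("sample ", f, " lacks energy or forces")
    attr(cfg, "forces") <- NULL; attr(cfg, "energy") <- NULL
    labeled_sample(cfg, en, fr)
  })
  structure(list(samples = samples, provenance = meta$provenance),
            class = "nr_dataset")
}
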