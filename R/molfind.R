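#' Bond-perception rules
#'
#' Two atoms are bonded when their minimum-image distance is strictly
#' smaller than `r_A + r_B + buffer`. The carbon radius of 0.85 A together
#' with the default 0.02 A buffer reproduces the 1.72 A C-C cutoff used
#' for ring scanning; H, N and O radii come from a standard covalent-radius
#' table (H adjusted to 0.37 A so that the H2 bond at 0.74 A is perceived).
#'
#' @param radii named covalent radii (A).
#' @param buffer additive buffer (A), default 0.02.
#' @return list of class `nr_bond_rules`.
#' @export
bond_rules <- function(radii = c(H = 0.37, C = 0.85, N = 0.71, O = 0.66),
                       buffer = 0.02) {
  if (any(radii <= 0)) stop("radii must be > 0")
  if (buffer < 0) stop("buffer must be >= 0")
  structure(list(radii = radii, buffer = buffer), class = "nr_bond_rules")
}

#' Bond cutoff for an element pair
#' @param rules an [bond_rules()].
#' @param a,b element symbols (vectorized).
#' @return cutoff distances (A).
#' @export
bond_cutoff <- function(rules, a, b) {
  ra <- rules$radii[a]; rb <- rules$radii[b]
  if (anyNA(ra) || anyNA(rb)) {
    bad <- unique(c(a[is.na(ra)], b[is.na(rb)]))
    stop("no covalent radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(ra + rb + rules$buffer)
}

#' Detect bonds in a configuration
#'
#' Builds the per-frame molecular bond graph: atoms are nodes (with their
#' element as attribute), edges join pairs whose minimum-image distance is
#' strictly below the per-pair cutoff.
#'
#' @param config an [configuration()].
#' @param rules an [bond_rules()] covering all elements present.
#' @return an `igraph` graph of class `nr_bondgraph` with vertex attribute
#'   `element` and edge attribute `dist`.
#' @export
detect_bonds <- function(config, rules = bond_rules()) {
  els <- unique(config$species)
  bond_cutoff(rules, els, els)  # validates coverage
  rmax <- max(outer(rules$radii[els], rules$radii[els], "+")) + rules$buffer
  np <- neighbor_pairs(config, rmax, multi_image = TRUE)
  if (nrow(np)) {
    cut <- bond_cutoff(rules, config$species[np$i], config$species[np$j])
    np <- np[np$dist < cut, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n_atoms(config), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = config$species)
  if (nrow(np)) {
    g <- igraph::add_edges(g, rbind(np$i, np$j), dist = np$dist)
  }
  class(g) <- c("nr_bondgraph", class(g))
  g
}

#' Extract molecules as connected components
#'
#' @param graph an [detect_bonds()] graph.
#' @return list of integer atom-index vectors, one per molecule, each
#'   sorted; molecules ordered by their smallest atom index.
#' @export
extract_molecules <- function(graph) {
  comp <- igraph::components(graph)
  mols <- split(seq_len(igraph::vcount(graph)), comp$membership)
  mols <- lapply(mols, sort)
  mols[order(vapply(mols, min, numeric(1)))]
}

# element order used in formulas and canonical keys (Hill-like for CHNO)
.element_rank <- c(C = 1L, H = 2L, N = 3L, O = 4L)

#' Molecular formula of an element multiset
#'
#' @param elements character vector of element symbols.
#' @return formula string in C, H, then alphabetical order (e.g. "CH4",
#'   "H2O").
#' @export
molecular_formula <- function(elements) {
  tab <- table(elements)
  nm <- names(tab)
  rank <- .element_rank[nm]
  rank[is.na(rank)] <- 100L + order(nm[is.na(rank)])
  nm <- nm[order(rank)]
  paste0(vapply(nm, function(e) {
    n <- tab[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

# canonical key format version; bump on any change to the key definition
NR_KEY_VERSION <- "nrk1"

#' Canonical topology key of a molecular graph
#'
#' A string invariant of the element-labeled graph: two components get
#' equal keys exactly when they are isomorphic as element-labeled graphs.
#' Built from the canonical vertex ordering (color-aware canonical
#' labeling, a refinement/backtracking algorithm), serializing the
#' canonically permuted element sequence and edge list, prefixed with a
#' format version so keys from different releases are never silently
#' compared.
#'
#' @param graph an igraph with vertex attribute `element` (typically one
#'   component of a bond graph, via [igraph::induced_subgraph()]).
#' @return character key.
#' @export
canonical_key <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("component is empty")
  els <- igraph::vertex_attr(graph, "element")
  colors <- .element_rank[els]
  colors[is.na(colors)] <- 50L
  cp <- igraph::canonical_permutation(graph, colors = as.integer(colors))
  gc <- igraph::permute(graph, cp$labeling)
  els_c <- igraph::vertex_attr(gc, "element")
  el <- igraph::as_edgelist(gc, names = FALSE)
  if (nrow(el)) {
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    estr <- paste(el[, 1], el[, 2], sep = "-", collapse = ",")
  } else estr <- ""
  paste0(NR_KEY_VERSION, "|", paste(els_c, collapse = "."), "|", estr)
}

# key + formula for every molecule of a bond graph
frame_species <- function(graph) {
  mols <- extract_molecules(graph)
  els <- igraph::vertex_attr(graph, "element")
  keys <- vapply(mols, function(idx)
    canonical_key(igraph::induced_subgraph(graph, idx)), character(1))
  formulas <- vapply(mols, function(idx) molecular_formula(els[idx]),
                     character(1))
  list(molecules = mols, keys = keys, formulas = formulas)
}

#' Census of unique species over a trajectory
#'
#' Detects bonds per frame, splits molecules, and counts topologically
#' distinct species via canonical keys. An optional lookup table (a
#' data.frame with columns `key` and `name`) annotates known topologies
#' with names.
#'
#' @param traj an [trajectory()] (or a single [configuration()]).
#' @param rules an [bond_rules()].
#' @param lookup optional data.frame with `key`, `name` columns.
#' @return object of class `nr_census`: list with `counts` (long tibble:
#'   frame, time, key, formula, count) and `species` (one row per species:
#'   key, formula, name, first_frame, last_frame, max_count).
#' @export
count_unique_species <- function(traj, rules = bond_rules(), lookup = NULL) {
  if (inherits(traj, "nr_config"))
    traj <- trajectory(list(traj), times = 0)
  rows <- vector("list", length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fs <- frame_species(detect_bonds(traj$frames[[f]], rules))
    if (length(fs$keys)) {
      tab <- table(fs$keys)
      form <- fs$formulas[match(names(tab), fs$keys)]
      rows[[f]] <- tibble::tibble(frame = f, time = traj$times[f],
                                  key = names(tab), formula = unname(form),
                                  count = as.integer(tab))
    }
  }
  counts <- dplyr::bind_rows(rows)
  if (nrow(counts) == 0L) {
    counts <- tibble::tibble(frame = integer(), time = numeric(),
                             key = character(), formula = character(),
                             count = integer())
  }
  species <- counts |>
    dplyr::group_by(.data$key, .data$formula) |>
    dplyr::summarise(first_frame = min(.data$frame),
                     last_frame = max(.data$frame),
                     max_count = max(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$first_frame, .data$formula)
  if (!is.null(lookup)) {
    species$name <- lookup$name[match(species$key, lookup$key)]
  } else {
    species$name <- NA_character_
  }
  structure(list(counts = counts, species = species,
                 key_version = NR_KEY_VERSION),
            class = "nr_census")
}

#' @export
print.nr_census <- function(x, ...) {
  cat(sprintf("<nr_census> %d distinct species over %d frames\n",
              nrow(x$species),
              if (nrow(x$counts)) max(x$counts$frame) else 0L))
  print(x$species)
  invisible(x)
}

#' Ring census via a minimum cycle basis
#'
#' Computes a minimum cycle basis per connected component (Horton
#' candidate cycles, greedy GF(2) independence) on the optionally
#' element-filtered subgraph, and tallies basis cycles by length over the
#' requested sizes.
#'
#' @param graph an [detect_bonds()] graph.
#' @param sizes ring sizes to report (default 3:7).
#' @param elements optional element filter (e.g. `"C"` for carbon-only
#'   ring scanning); default all atoms.
#' @return named integer vector, one entry per requested size.
#' @export
ring_census <- function(graph, sizes = 3:7, elements = NULL) {
  g <- graph
  if (!is.null(elements)) {
    keep <- which(igraph::vertex_attr(g, "element") %in% elements)
    g <- igraph::induced_subgraph(g, keep)
  }
  out <- stats::setNames(integer(length(sizes)), as.character(sizes))
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == cid))
    lens <- min_cycle_basis_lengths(sub)
    for (L in lens) {
      key <- as.character(L)
      if (key %in% names(out)) out[key] <- out[key] + 1L
    }
  }
  out
}

# Lengths of a minimum cycle basis of a connected graph (Horton's
# algorithm with greedy GF(2) elimination over edge space).
min_cycle_basis_lengths <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  dim_cycles <- m - n + 1L
  if (dim_cycles <= 0L) return(integer(0))
  el <- igraph::as_edgelist(g, names = FALSE)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  # Horton candidates: for each vertex v and edge (x, y):
  # cycle = sp(v, x) + (x, y) + sp(y, v), when paths are disjoint
  cands <- list()
  sp_all <- igraph::distances(g)
  for (v in seq_len(n)) {
    paths <- igraph::shortest_paths(g, from = v, to = seq_len(n))$vpath
    for (e in seq_len(m)) {
      x <- el[e, 1]; y <- el[e, 2]
      px <- as.integer(paths[[x]]); py <- as.integer(paths[[y]])
      if (!length(px) || !length(py)) next
      shared <- intersect(px[-1], py[-1])
      if (length(shared)) next                  # paths must only share v
      verts <- c(px, rev(py))
      if (length(unique(verts[-length(verts)])) != length(verts) - 1L) next
      cyc_edges <- cycle_edge_ids(verts, ekey)
      if (is.null(cyc_edges) || length(cyc_edges) < 3L) next
      cands[[length(cands) + 1L]] <-
        list(len = length(cyc_edges), edges = cyc_edges)
    }
  }
  if (!length(cands)) return(integer(0))
  # dedupe and sort by length
  sig <- vapply(cands, function(c) paste(sort(c$edges), collapse = ","),
                character(1))
  cands <- cands[!duplicated(sig)]
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "len"))]
  basis_lens <- integer(0)
  reduced <- list()   # reduced edge-set vectors (logical over m)
  for (cand in cands) {
    vec <- logical(m)
    vec[cand$edges] <- TRUE
    # reduce against current basis
    for (b in reduced) {
      pivot <- which(b)[1]
      if (vec[pivot]) vec <- xor(vec, b)
    }
    if (any(vec)) {
      reduced[[length(reduced) + 1L]] <- vec
      basis_lens <- c(basis_lens, cand$len)
      if (length(basis_lens) == dim_cycles) break
    }
  }
  basis_lens
}

# map a closed vertex walk (v1..vk, v1 = vk implied closure via last-first
# edge) to edge indices; verts is the cycle with v repeated at both ends
cycle_edge_ids <- function(verts, ekey) {
  k <- length(verts)
  a <- verts[-k]; b <- verts[-1]
  keys <- paste(pmin(a, b), pmax(a, b))
  ids <- match(keys, ekey)
  if (anyNA(ids)) return(NULL)
  unique(ids)
}

#' Track species counts over a trajectory
#'
#' Counts molecules matching each target per frame. Formula targets (e.g.
#' `"CO2"`) match on composition; key targets (strings starting with the
#' key version prefix) match on topology.
#'
#' @param traj an [trajectory()].
#' @param rules an [bond_rules()].
#' @param targets character vector of formulas and/or canonical keys.
#' @return tibble with columns `frame`, `time`, `target`, `count`, of
#'   class `nr_species_series`.
#' @export
track_species <- function(traj, rules = bond_rules(), targets) {
  if (!is.character(targets) || !length(targets))
    stop("targets must be a character vector of formulas or canonical keys")
  is_key <- startsWith(targets, NR_KEY_VERSION)
  bad <- !is_key & !grepl("^([A-Z][a-z]?[0-9]*)+$", targets)
  if (any(bad))
    stop("unrecognized target format: ", paste(targets[bad], collapse = ", "))
  # normalize formula targets to canonical formula strings
  norm <- targets
  for (t in which(!is_key)) {
    parts <- gregexpr("[A-Z][a-z]?[0-9]*", targets[t])[[1]]
    toks <- regmatches(targets[t], gregexpr("[A-Z][a-z]?[0-9]*", targets[t]))[[1]]
    els <- unlist(lapply(toks, function(tok) {
      el <- gsub("[0-9]", "", tok)
      nrep <- as.integer(gsub("[A-Za-z]", "", tok))
      if (is.na(nrep)) nrep <- 1L
      rep(el, nrep)
    }))
    norm[t] <- molecular_formula(els)
  }
  rows <- vector("list", length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fs <- frame_species(detect_bonds(traj$frames[[f]], rules))
    cnt <- vapply(seq_along(targets), function(ti) {
      if (is_key[ti]) sum(fs$keys == targets[ti])
      else sum(fs$formulas == norm[ti])
    }, integer(1))
    rows[[f]] <- tibble::tibble(frame = f, time = traj$times[f],
                                target = targets, count = cnt)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nr_species_series", class(out))
  out
}

#' Ignition delay time
#'
#' The mean, over CO, CO2 and H2O, of the first time each species' count
#' reaches the threshold (default 5 molecules). Returns `NA` when any of
#' the three species never crosses.
#'
#' @param series an [track_species()] result containing targets `CO`,
#'   `CO2` and `H2O` (or a tibble with `time`, `target`, `count`).
#' @param threshold molecule-count threshold (default 5).
#' @param species the three species averaged (override for other
#'   chemistries).
#' @return IDT in the series' time units (fs), or `NA_real_`.
#' @export
ignition_delay_time <- function(series, threshold = 5,
                                species = c("CO", "CO2", "H2O")) {
  miss <- setdiff(species, unique(series$target))
  if (length(miss))
    stop("series lacks target(s): ", paste(miss, collapse = ", "))
  grids <- lapply(species, function(s) series$time[series$target == s])
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(grids[[1]], g)))
      stop("species series are on mismatched time grids")
  }
  crossing <- vapply(species, function(s) {
    sub <- series[series$target == s, ]
    sub <- sub[order(sub$time), ]
    hit <- which(sub$count >= threshold)
    if (!length(hit)) NA_real_ else sub$time[hit[1]]
  }, numeric(1))
  if (anyNA(crossing)) return(NA_real_)
  mean(crossing)
}
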