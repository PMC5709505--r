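#' Write an embedded network to plain-text files
#'
#' Two tab-separated files: an edge list (`node_id_a <tab> node_id_b`, one
#' unordered edge per row, no duplicates, no header) and a coordinate table
#' (`node_id <tab> r <tab> theta`, one row per node, theta in radians in
#' `[0, 2*pi)`, no header). This layout matches the output of published
#' hyperbolic-embedding tools, so precomputed maps of real networks load
#' without conversion.
#'
#' @param network an embedded network.
#' @param edge_path,coord_path output file paths.
#' @return invisibly, the network.
#' @export
write_embedded_network <- function(network, edge_path, coord_path) {
  assert_embedded(network)
  ids <- igraph::V(network)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(network)))
  el <- igraph::as_edgelist(network, names = FALSE)
  utils::write.table(
    data.frame(a = ids[el[, 1]], b = ids[el[, 2]]),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(id = ids,
               r = format(igraph::V(network)$r, digits = 15),
               theta = format(igraph::V(network)$theta, digits = 15)),
    coord_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(network)
}

#' Read an embedded network from plain-text files
#'
#' Reads the edge-list / coordinate-table pair written by
#' [write_embedded_network()] (or by external hyperbolic-embedding tools
#' using the same layout; extra columns after the third in the coordinate
#' table are ignored). Node ids may be arbitrary strings. Validation:
#' duplicate coordinate rows and edges with endpoints missing from the
#' coordinate table are errors; angles must be in radians — values outside
#' `[-2*pi, 2*pi)` are rejected as likely degrees — and are wrapped into
#' `[0, 2*pi)`. The graph attribute `disc_radius` is set to the largest
#' radial coordinate.
#'
#' @param edge_path,coord_path input file paths.
#' @return an embedded network.
#' @export
read_embedded_network <- function(edge_path, coord_path) {
  coords <- utils::read.delim(coord_path, header = FALSE,
                              colClasses = "character",
                              stringsAsFactors = FALSE)
  if (ncol(coords) < 3)
    stop("coordinate table must have at least three tab-separated columns: id, r, theta")
  coords <- data.frame(id = coords[[1]],
                       r = as.numeric(coords[[2]]),
                       theta = as.numeric(coords[[3]]),
                       stringsAsFactors = FALSE)
  if (anyNA(coords$r) || anyNA(coords$theta))
    stop("non-numeric r/theta values in the coordinate table")
  if (anyDuplicated(coords$id))
    stop("duplicate coordinate rows for node id(s): ",
         paste(unique(coords$id[duplicated(coords$id)]), collapse = ", "))
  if (any(coords$r < 0)) stop("radial coordinates must be nonnegative")
  th <- coords$theta
  if (any(abs(th) >= 2 * pi + 1e-9))
    stop("angular coordinates outside [-2*pi, 2*pi) found; theta must be in radians, not degrees")
  th <- th %% (2 * pi)
  edges <- utils::read.delim(edge_path, header = FALSE,
                             colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list must have two tab-separated columns")
  idx <- setNames(seq_along(coords$id), coords$id)
  bad <- setdiff(unique(c(edges[[1]], edges[[2]])), coords$id)
  if (length(bad))
    stop("edge endpoints without a coordinate row: ", paste(bad, collapse = ", "))
  el <- cbind(idx[edges[[1]]], idx[edges[[2]]])
  embedded_network(el, coords$r, th, disc_radius = max(coords$r),
                   node_ids = coords$id)
}

#' Write / read a strategy snapshot
#'
#' Tab-separated, one row per node: `node_id <tab> strategy`, strategy coded
#' 1 = cooperate, 0 = defect, no header.
#'
#' @param strategies a [strategy_state()] or logical vector.
#' @param path file path.
#' @param node_ids optional node ids; defaults to `1...N`.
#' @return `write_strategies` invisibly returns `strategies`;
#'   `read_strategies` returns a named logical vector.
#' @export
write_strategies <- function(strategies, path, node_ids = NULL) {
  s <- as_strategy(strategies)
  if (is.null(node_ids)) node_ids <- as.character(seq_along(s))
  utils::write.table(data.frame(id = node_ids, strategy = as.integer(s)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(strategies)
}

#' @rdname write_strategies
#' @export
read_strategies <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         colClasses = c("character", "integer"))
  setNames(d[[2]] == 1L, d[[1]])
}

#' Write a trajectory to CSV
#'
#' Columns `generation`, `coop_density`, `ks_stat` (`NA` where the KS
#' recorder did not fire or was off) and `absorbed` (0/1 flag from the
#' absorption generation onward).
#'
#' @param trajectory a `trajectory` from [run_simulation()].
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  gen <- trajectory$generations
  ks <- rep(NA_real_, length(gen))
  if (!is.null(trajectory$ks))
    ks[match(trajectory$ks$generation, gen)] <- trajectory$ks$rho_bar
  absorbed <- if (is.na(trajectory$absorbed_at)) rep(0L, length(gen))
  else as.integer(gen >= trajectory$absorbed_at)
  d <- data.frame(generation = gen, coop_density = trajectory$coop_density,
                  ks_stat = ks, absorbed = absorbed)
  write_results(d, path)
  invisible(d)
}

#' Write a tidy results table to CSV
#'
#' Comma-separated, UTF-8, header row, locale-independent decimal point,
#' no row names; numeric values keep 15 significant digits so a round-trip
#' preserves them to at least 12.
#'
#' @param table a data frame (one row per observation; may be empty).
#' @param path output path.
#' @return invisibly, `table`.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  tab <- table
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' Run manifest
#'
#' A reproducibility record for an experiment: the full parameter set, the
#' root seed and the derived per-realization seeds, the package version, and
#' a timestamp. The manifest together with the configuration suffices to
#' reproduce any output bit-identically (timestamps live only here, never in
#' data files).
#'
#' @param parameters named list echoing the experiment configuration.
#' @param root_seed integer root seed.
#' @param n_realizations number of realizations (determines the derived
#'   seeds recorded).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(parameters, root_seed, n_realizations) {
  structure(list(parameters = parameters,
                 root_seed = as.integer(root_seed),
                 per_realization_seeds = derive_seeds(root_seed, n_realizations),
                 artifact_version = as.character(utils::packageVersion("hypercoop")),
                 timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output path for the JSON manifest.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
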