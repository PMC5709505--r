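#' Final cooperation density over independent realizations
#'
#' Runs the full pipeline — generate a network, take its giant component,
#' seed the initial cooperators, run the synchronous Fermi dynamics — once
#' per realization and reports the final cooperation densities. By default
#' each realization uses a freshly generated network ("realizations of the
#' system"); set `fixed_network = TRUE` (or pass an igraph object as
#' `network`) to rerun the dynamics on one network.
#'
#' @param network_params a [network_params()] object, or an igraph object to
#'   use as a fixed network for all realizations.
#' @param game_params a [game_params()] object.
#' @param seed_spec a [seed_spec()].
#' @param horizon number of generations per realization.
#' @param n_realizations number of independent realizations.
#' @param root_seed integer root seed; child seeds are derived
#'   deterministically per realization. `NULL` uses the current RNG stream.
#' @param fixed_network if `TRUE`, generate one network (from the first
#'   derived seed) and reuse it across realizations.
#' @return a list with `mean`, `sd`, numeric vector `finals`, and a tidy
#'   data frame `table` (realization, final_coop, horizon).
#' @export
final_cooperation <- function(network_params, game_params, seed_spec, horizon,
                              n_realizations, root_seed = NULL,
                              fixed_network = FALSE) {
  stopifnot(inherits(game_params, "game_params"), inherits(seed_spec, "seed_spec"))
  seeds <- derive_seeds(root_seed, n_realizations + 1L)
  g_fixed <- NULL
  if (igraph::is_igraph(network_params)) {
    g_fixed <- network_params
  } else if (fixed_network) {
    p <- network_params; p$seed <- seeds[n_realizations + 1L]
    g_fixed <- giant_component(generate_network(p))
  }
  finals <- vapply(seq_len(n_realizations), function(i) {
    set.seed(seeds[i])
    g <- if (!is.null(g_fixed)) g_fixed else {
      p <- network_params; p$seed <- NULL
      giant_component(generate_network(p))
    }
    init <- apply_seeding(g, seed_spec)
    final_density(run_simulation(g, init, game_params, horizon))
  }, 1.0)
  list(mean = mean(finals), sd = if (n_realizations > 1) sd(finals) else NA_real_,
       finals = finals,
       table = data.frame(realization = seq_len(n_realizations),
                          final_coop = finals, horizon = horizon))
}

#' Classify a phase-diagram region from seeding outcomes
#'
#' Given whether the mean final cooperation exceeded the threshold under
#' random, hub and metric-cluster seeding, returns the region label used in
#' the game-parameter phase diagrams: `"always"` (all three pass),
#' `"hubs_or_metric"`, `"hubs_only"`, `"metric_only"`, `"none"`, and
#' `"other"` for the remaining combinations (random passing while a targeted
#' scheme fails), which do not occur in practice.
#'
#' @param random_pass,hubs_pass,metric_pass logical vectors (recycled).
#' @return character vector of region labels.
#' @export
classify_region <- function(random_pass, hubs_pass, metric_pass) {
  m <- max(length(random_pass), length(hubs_pass), length(metric_pass))
  r <- rep_len(as.logical(random_pass), m)
  h <- rep_len(as.logical(hubs_pass), m)
  k <- rep_len(as.logical(metric_pass), m)
  out <- rep("other", m)
  out[r & h & k] <- "always"
  out[!r & h & k] <- "hubs_or_metric"
  out[!r & h & !k] <- "hubs_only"
  out[!r & !h & k] <- "metric_only"
  out[!r & !h & !k] <- "none"
  out
}

# internal: run final_cooperation over a data frame of cells, one derived
# seed per cell, returning one row per realization
run_cells <- function(cells, make_params, game_params_fun, schemes, horizon,
                      n_realizations, root_seed, density = 0.5) {
  cell_grid <- merge(cells, data.frame(scheme = schemes, stringsAsFactors = FALSE))
  seeds <- derive_seeds(root_seed, nrow(cell_grid))
  rows <- lapply(seq_len(nrow(cell_grid)), function(i) {
    row <- cell_grid[i, , drop = FALSE]
    fc <- final_cooperation(make_params(row), game_params_fun(row),
                            seed_spec(row$scheme, density = density),
                            horizon, n_realizations, root_seed = seeds[i])
    cbind(row[rep(1, n_realizations), , drop = FALSE], fc$table,
          row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Game-parameter (T-S) phase sweep
#'
#' Runs [final_cooperation()] for every combination of temptation, sucker's
#' payoff and seeding scheme on a grid of game parameters, and classifies
#' each (T, S) point by which seeding schemes drive the mean final
#' cooperation above the threshold.
#'
#' The sweep is deterministic given `root_seed`: every (T, S, scheme) cell
#' gets its own derived child seed, so re-running any cell reproduces its
#' rows bit-identically. The region map is a pure function of the tidy table
#' and the threshold.
#'
#' @param temptation_values,sucker_values numeric grids of game parameters.
#' @param network_source a [network_params()] object (fresh network per
#'   realization) or an igraph object (fixed network).
#' @param schemes seeding schemes to compare; regions are derived when
#'   `"random"`, `"hubs"` and `"metric_cluster"` are all present.
#' @param horizon generations per run.
#' @param n_realizations realizations per cell.
#' @param root_seed integer root seed (`NULL`: current RNG stream).
#' @param threshold cooperation threshold for region classification
#'   (default 0.3).
#' @param noise Fermi selection noise `K` (default 0.5).
#' @param density initial cooperation density (default 0.5).
#' @return a list with the tidy `table` (one row per point x scheme x
#'   realization), the per-point `summary` (mean final cooperation), the
#'   `regions` data frame (or `NULL`), and the `threshold`.
#' @export
ts_phase_sweep <- function(temptation_values, sucker_values, network_source,
                           schemes = c("random", "hubs", "metric_cluster"),
                           horizon, n_realizations, root_seed = NULL,
                           threshold = 0.3, noise = 0.5, density = 0.5) {
  cells <- expand.grid(temptation = temptation_values, sucker = sucker_values,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- run_cells(cells,
                   make_params = function(row) network_source,
                   game_params_fun = function(row)
                     game_params(row$temptation, row$sucker, noise),
                   schemes, horizon, n_realizations, root_seed, density)
  summ <- stats::aggregate(final_coop ~ temptation + sucker + scheme, tab, mean)
  regions <- NULL
  canonical <- c("random", "hubs", "metric_cluster")
  if (all(canonical %in% schemes)) {
    wide <- stats::reshape(summ[summ$scheme %in% canonical, ],
                           idvar = c("temptation", "sucker"),
                           timevar = "scheme", direction = "wide")
    rp <- wide$final_coop.random > threshold
    hp <- wide$final_coop.hubs > threshold
    mp <- wide$final_coop.metric_cluster > threshold
    regions <- data.frame(temptation = wide$temptation, sucker = wide$sucker,
                          random_pass = rp, hubs_pass = hp, metric_pass = mp,
                          label = classify_region(rp, hp, mp))
  }
  list(table = tab, summary = summ, regions = regions, threshold = threshold)
}

#' Heterogeneity-clustering sweep
#'
#' Final cooperation over a grid of degree-distribution exponents `gamma`
#' and target mean local clustering values, for one or more seeding schemes.
#' Each clustering target is first inverted to a graph temperature with
#' [calibrate_temperature()]; cells whose target is not achievable are
#' skipped with a warning.
#'
#' @param gamma_values numeric vector of power-law exponents (> 2).
#' @param clustering_values numeric vector of target mean local clustering.
#' @param n_nodes,kbar network size and target mean degree.
#' @param game_params a [game_params()] object.
#' @param schemes seeding schemes.
#' @param horizon,n_realizations,root_seed as in [ts_phase_sweep()].
#' @param calib_pilots,calib_tol calibration settings (see
#'   [calibrate_temperature()]).
#' @param density initial cooperation density.
#' @return a tidy data frame with one row per cell x scheme x realization,
#'   including the calibrated `temperature`.
#' @export
gamma_clustering_sweep <- function(gamma_values, clustering_values, n_nodes,
                                   kbar, game_params,
                                   schemes = c("random", "hubs", "metric_cluster"),
                                   horizon, n_realizations, root_seed = NULL,
                                   calib_pilots = 2, calib_tol = 0.02,
                                   density = 0.5) {
  cells <- expand.grid(gamma = gamma_values,
                       target_clustering = clustering_values,
                       KEEP.OUT.ATTRS = FALSE)
  calib_seeds <- derive_seeds(if (is.null(root_seed)) NULL else root_seed + 1L,
                              nrow(cells))
  cells$temperature <- vapply(seq_len(nrow(cells)), function(i) {
    set.seed(calib_seeds[i])
    tryCatch(
      calibrate_temperature(cells$target_clustering[i],
                            network_params(n_nodes, cells$gamma[i], kbar),
                            pilot_realizations = calib_pilots, tol = calib_tol),
      error = function(e) {
        warning(sprintf("skipping cell gamma=%g, clustering=%g: %s",
                        cells$gamma[i], cells$target_clustering[i],
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
  }, 1.0)
  cells <- cells[!is.na(cells$temperature), , drop = FALSE]
  if (nrow(cells) == 0) return(cells)
  run_cells(cells,
            make_params = function(row)
              network_params(n_nodes, row$gamma, kbar, row$temperature),
            game_params_fun = function(row) game_params,
            schemes, horizon, n_realizations, root_seed, density)
}

#' Metric-cluster size scaling experiment
#'
#' Final cooperation when the initial cooperators are split into
#' `n_clusters` disjoint metric clusters, across network sizes. The
#' per-cluster absolute size `n_nodes / (2 * n_clusters)` is included so
#' that curves for different network sizes can be overlaid against it (they
#' collapse when cluster survival depends on absolute cluster size).
#'
#' @param n_nodes_values,n_clusters_values grids of network sizes and
#'   cluster counts.
#' @param gamma,temperature,kbar network model parameters.
#' @param game_params a [game_params()] object.
#' @param horizon,n_realizations,root_seed as in [ts_phase_sweep()].
#' @return a tidy data frame with columns `n_nodes`, `n_clusters`,
#'   `cluster_size`, `realization`, `final_coop`, `horizon`.
#' @export
cluster_scaling_experiment <- function(n_nodes_values, n_clusters_values,
                                       gamma, temperature, kbar, game_params,
                                       horizon, n_realizations,
                                       root_seed = NULL) {
  cells <- expand.grid(n_nodes = n_nodes_values, n_clusters = n_clusters_values,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(root_seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, , drop = FALSE]
    fc <- final_cooperation(
      network_params(row$n_nodes, gamma, kbar, temperature),
      game_params,
      seed_spec("multiple_metric_clusters", n_clusters = row$n_clusters),
      horizon, n_realizations, root_seed = seeds[i])
    cbind(row[rep(1, n_realizations), , drop = FALSE],
          cluster_size = floor(row$n_nodes / (2 * row$n_clusters)),
          fc$table, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Intercluster-link fraction experiment
#'
#' Measures, with no game dynamics involved, the fraction of links leaving
#' a metric cluster spanning half of the network (metric-cluster seeding at
#' density 0.5 on the giant component) over a grid of network sizes,
#' exponents and temperatures.
#'
#' @param n_nodes_values,gamma_values,temperature_values grids of model
#'   parameters (crossed).
#' @param kbar target mean degree.
#' @param n_seeds networks generated per cell.
#' @param root_seed integer root seed.
#' @param density cluster density (default 0.5, half of the network).
#' @return a list with the per-network `table` and the per-cell `summary`
#'   (mean and sd of the link fraction).
#' @export
intercluster_link_experiment <- function(n_nodes_values, gamma_values,
                                         temperature_values, kbar = 6,
                                         n_seeds = 5, root_seed = NULL,
                                         density = 0.5) {
  cells <- expand.grid(n_nodes = n_nodes_values, gamma = gamma_values,
                       temperature = temperature_values, KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(root_seed, nrow(cells) * n_seeds)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, , drop = FALSE]
    fr <- vapply(seq_len(n_seeds), function(j) {
      set.seed(seeds[(i - 1L) * n_seeds + j])
      g <- giant_component(generate_network(
        network_params(row$n_nodes, row$gamma, kbar, row$temperature)))
      intercluster_link_fraction(g, seed_metric_cluster(g, density))
    }, 1.0)
    cbind(row[rep(1, n_seeds), , drop = FALSE],
          seed_index = seq_len(n_seeds), link_fraction = fr, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(link_fraction ~ n_nodes + gamma + temperature, tab,
                           function(x) c(mean = mean(x), sd = sd(x)))
  summ <- do.call(data.frame, summ)
  names(summ) <- c("n_nodes", "gamma", "temperature",
                   "link_fraction_mean", "link_fraction_sd")
  list(table = tab, summary = summ)
}
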