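#' Parameters of the hyperbolic network model
#'
#' Bundles the parameters of the temperature-controlled hyperbolic random
#' graph model: nodes are placed on a disc of radius `R` (see
#' [disc_radius()]), with angular (similarity) coordinates uniform on
#' `[0, 2*pi)` and radial (popularity) coordinates from an exponential-like
#' density controlled by the degree-distribution exponent `gamma`; pairs are
#' connected with a Fermi-Dirac probability of their hyperbolic distance.
#'
#' @param n_nodes positive integer, number of nodes `N`.
#' @param gamma power-law exponent of the degree distribution; must exceed 2.
#' @param kbar_target target mean degree; controls the disc radius.
#' @param temperature graph temperature in the open interval (0, 1). Low
#'   values give strong metric structure and high mean local clustering;
#'   high values add random long-range links. May be `NA` when the object is
#'   only used as a base for [calibrate_temperature()].
#' @param seed optional integer seed used by [generate_network()]; when
#'   `NULL` the current RNG state is used.
#' @return an object of class `network_params`.
#' @seealso [generate_network()], [disc_radius()], [calibrate_temperature()]
#' @export
#' @examples
#' network_params(n_nodes = 500, gamma = 2.6, kbar_target = 6, temperature = 0.3)
network_params <- function(n_nodes, gamma, kbar_target, temperature = NA_real_,
                           seed = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("`n_nodes` must be a single integer >= 2")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 2)
    stop("`gamma` must be > 2 (the radial density and disc radius diverge at gamma = 2)")
  if (!is.numeric(kbar_target) || length(kbar_target) != 1L || kbar_target <= 0)
    stop("`kbar_target` must be a positive real")
  if (!is.na(temperature) &&
      (!is.numeric(temperature) || length(temperature) != 1L ||
       temperature <= 0 || temperature >= 1))
    stop("`temperature` must lie in the open interval (0, 1): sin(temperature * pi) must be positive")
  structure(
    list(n_nodes = as.integer(n_nodes), gamma = as.numeric(gamma),
         kbar_target = as.numeric(kbar_target),
         temperature = as.numeric(temperature), seed = seed),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("Hyperbolic network model parameters\n")
  cat(sprintf("  N = %d, gamma = %g, target mean degree = %g, temperature = %s\n",
              x$n_nodes, x$gamma, x$kbar_target,
              if (is.na(x$temperature)) "<uncalibrated>" else format(x$temperature)))
  invisible(x)
}

#' Parameters of the 2x2 social dilemma
#'
#' The game is the conventional two-parameter normalisation of the 2x2
#' payoff matrix: mutual cooperation pays 1, mutual defection pays 0, a
#' cooperator facing a defector receives the sucker's payoff `S` and the
#' defector the temptation `T`. The quadrants of the (T, S) plane give the
#' harmony game (T < 1, S > 0), stag hunt (T < 1, S < 0), snowdrift
#' (T > 1, S > 0) and the prisoner's dilemma (T > 1, S < 0).
#'
#' @param temptation payoff `T` to a defector exploiting a cooperator.
#' @param sucker payoff `S` to a cooperator exploited by a defector.
#' @param noise selection noise `K` of the Fermi imitation rule (the
#'   "irrationality" of players); must be positive. Default 0.5.
#' @return an object of class `game_params`.
#' @export
#' @examples
#' game_params(temptation = 1.2, sucker = -0.2)
game_params <- function(temptation, sucker, noise = 0.5) {
  stopifnot(is.numeric(temptation), length(temptation) == 1L,
            is.numeric(sucker), length(sucker) == 1L)
  if (!is.numeric(noise) || length(noise) != 1L || noise <= 0)
    stop("`noise` (K) must be a positive real")
  structure(list(temptation = as.numeric(temptation),
                 sucker = as.numeric(sucker), noise = as.numeric(noise)),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  quad <- if (x$temptation > 1 && x$sucker < 0) "prisoner's dilemma"
  else if (x$temptation > 1 && x$sucker > 0) "snowdrift"
  else if (x$temptation < 1 && x$sucker < 0) "stag hunt"
  else if (x$temptation < 1 && x$sucker > 0) "harmony"
  else "boundary game"
  cat(sprintf("2x2 game: T = %g, S = %g, K = %g (%s)\n",
              x$temptation, x$sucker, x$noise, quad))
  invisible(x)
}

#' Specification of an initial-cooperator configuration
#'
#' Names one of the five seeding procedures together with its parameters.
#' See [apply_seeding()] for the procedures themselves.
#'
#' @param scheme one of `"random"`, `"hubs"`, `"metric_cluster"`,
#'   `"multiple_metric_clusters"`, `"connected_cluster"`.
#' @param density initial cooperation density `c(0)` in (0, 1); default 0.5.
#'   Ignored by `connected_cluster`, which takes an explicit size.
#' @param n_clusters number of disjoint metric clusters (only for
#'   `multiple_metric_clusters`).
#' @param cluster_size target size of the connected cooperator cluster (only
#'   for `connected_cluster`); defaults to `density * N` at seeding time.
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(scheme = c("random", "hubs", "metric_cluster",
                                 "multiple_metric_clusters", "connected_cluster"),
                      density = 0.5, n_clusters = NULL, cluster_size = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]")
  if (scheme == "multiple_metric_clusters") {
    if (is.null(n_clusters) || n_clusters < 1)
      stop("`n_clusters` (>= 1) is required for the multiple_metric_clusters scheme")
    n_clusters <- as.integer(n_clusters)
  }
  structure(list(scheme = scheme, density = density,
                 n_clusters = n_clusters, cluster_size = cluster_size),
            class = "seed_spec")
}

# internal: derive reproducible child seeds from a root seed without
# disturbing the caller's RNG state; NULL root draws from the current stream.
derive_seeds <- function(root_seed, n) {
  if (is.null(root_seed)) return(sample.int(.Machine$integer.max, n))
  withr::with_seed(as.integer(root_seed),
                   sample.int(.Machine$integer.max, n))
}
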