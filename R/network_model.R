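#' Radius of the hyperbolic disc
#'
#' The disc radius that yields a target mean degree in the hyperbolic random
#' graph model:
#' `R = 2 * log( 2 * temperature * N / (kbar * sin(temperature * pi)) * ((gamma - 1)/(gamma - 2))^2 )`.
#' `R` grows logarithmically with `N`; doubling `N` shifts it by exactly
#' `2 * log(2)`.
#'
#' @param params a [network_params()] object with a non-`NA` temperature.
#' @return the disc radius, a positive real in hyperbolic units.
#' @export
#' @examples
#' disc_radius(network_params(2000, gamma = 2.6, kbar_target = 6, temperature = 0.3))
disc_radius <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (is.na(params$temperature))
    stop("`temperature` is NA; set it or calibrate it first")
  with(params, 2 * log(2 * temperature * n_nodes /
                         (kbar_target * sin(temperature * pi)) *
                         ((gamma - 1) / (gamma - 2))^2))
}

#' Sample node coordinates on the hyperbolic disc
#'
#' Angular coordinates are i.i.d. uniform on `[0, 2*pi)`. Radial coordinates
#' follow the density `rho(r) = a * exp(a * (r - R))` with
#' `a = (gamma - 1)/2`, truncated to `[0, R]` and sampled by exact inversion
#' of the truncated CDF, so that no radius exceeds the disc radius.
#'
#' Uses the current R RNG stream; call `set.seed()` for reproducibility.
#'
#' @param params a [network_params()] object.
#' @param disc_radius the disc radius, typically from [disc_radius()].
#' @return a list with numeric vectors `radial` and `angular` of length
#'   `params$n_nodes`.
#' @export
sample_coordinates <- function(params, disc_radius) {
  stopifnot(inherits(params, "network_params"), disc_radius > 0)
  n <- params$n_nodes
  a <- (params$gamma - 1) / 2
  u <- runif(n)
  # inverse of F(r) = (exp(a (r - R)) - exp(-a R)) / (1 - exp(-a R)) on [0, R]
  e0 <- exp(-a * disc_radius)
  radial <- disc_radius + log(u * (1 - e0) + e0) / a
  radial <- pmin(pmax(radial, 0), disc_radius)
  angular <- runif(n, 0, 2 * pi)
  list(radial = radial, angular = angular)
}

#' Hyperbolic distance between points on the disc
#'
#' Distance in the native hyperbolic plane,
#' `x = acosh(cosh(r1) cosh(r2) - sinh(r1) sinh(r2) cos(dtheta))` with the
#' angular separation `dtheta = pi - |pi - |theta1 - theta2||`. For large
#' radii (sum above 60, where the cosh product approaches double-precision
#' limits) the standard asymptotic form
#' `x ~ r1 + r2 + 2 log(sin(dtheta / 2))`, clipped below at `|r1 - r2|`, is
#' used; the two forms agree to well below 1e-3 at the crossover.
#'
#' All arguments are recycled to a common length.
#'
#' @param r1,theta1 polar coordinates of the first point(s); radii must be
#'   nonnegative, angles in radians.
#' @param r2,theta2 polar coordinates of the second point(s).
#' @return nonnegative numeric vector of distances.
#' @export
#' @examples
#' hyperbolic_distance(5, 0, 5, pi)     # diametrically opposite
#' hyperbolic_distance(3, 1, 7, 1)      # same angle: |r1 - r2|
hyperbolic_distance <- function(r1, theta1, r2, theta2) {
  m <- max(length(r1), length(theta1), length(r2), length(theta2))
  r1 <- rep_len(r1, m); r2 <- rep_len(r2, m)
  theta1 <- rep_len(theta1, m); theta2 <- rep_len(theta2, m)
  if (any(r1 < 0) || any(r2 < 0)) stop("radial coordinates must be nonnegative")
  dth <- pi - abs(pi - abs(theta1 - theta2))
  out <- numeric(m)
  zero <- dth <= 0
  out[zero] <- abs(r1[zero] - r2[zero])
  big <- !zero & (r1 + r2 >= 60)
  if (any(big)) {
    x <- r1[big] + r2[big] + 2 * log(sin(dth[big] / 2))
    out[big] <- pmax(x, abs(r1[big] - r2[big]))
  }
  rest <- !zero & !big
  if (any(rest)) {
    arg <- cosh(r1[rest]) * cosh(r2[rest]) -
      sinh(r1[rest]) * sinh(r2[rest]) * cos(dth[rest])
    out[rest] <- acosh(pmax(arg, 1))
  }
  out
}

#' Fermi-Dirac connection probability
#'
#' Probability that two nodes at hyperbolic distance `x` are linked:
#' `p(x) = 1 / (1 + exp((x - R) / (2 * temperature)))`. Strictly decreasing
#' in `x`, equal to 1/2 at `x = R`. The temperature controls how sharply the
#' probability decays around the disc radius and hence the amount of random
#' long-range links (and, inversely, the mean local clustering).
#'
#' @param distance nonnegative hyperbolic distance(s).
#' @param disc_radius disc radius `R`.
#' @param temperature graph temperature in (0, 1).
#' @return probabilities in `[0, 1]`.
#' @export
connection_probability <- function(distance, disc_radius, temperature) {
  if (temperature <= 0 || temperature >= 1)
    stop("`temperature` must lie in the open interval (0, 1)")
  plogis(-(distance - disc_radius) / (2 * temperature))
}

#' Construct an embedded network
#'
#' Builds the central data object: an undirected simple [igraph][igraph::igraph-package]
#' graph whose vertices carry polar coordinates on the hyperbolic disc
#' (vertex attributes `r` and `theta`) and whose graph attribute
#' `disc_radius` records the disc radius. Vertex names are the node ids.
#'
#' @param edges two-column matrix or data frame of 1-based node indices (or
#'   a zero-row matrix for an edgeless graph).
#' @param radial numeric vector of radial coordinates, one per node, each in
#'   `[0, disc_radius]`.
#' @param angular numeric vector of angular coordinates in `[0, 2*pi)`.
#' @param disc_radius positive disc radius.
#' @param node_ids optional character vector of node names; defaults to
#'   `"1" ... "N"`.
#' @return an igraph object with the embedding attached.
#' @export
embedded_network <- function(edges, radial, angular, disc_radius,
                             node_ids = NULL) {
  n <- length(radial)
  if (length(angular) != n)
    stop("`radial` and `angular` must have the same length")
  if (any(radial < 0) || any(radial > disc_radius + 1e-9))
    stop("radial coordinates must lie in [0, disc_radius]")
  if (any(angular < 0) || any(angular >= 2 * pi))
    stop("angular coordinates must lie in [0, 2*pi)")
  edges <- as.matrix(edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges < 1) || any(edges > n)) stop("edge endpoints out of range")
    g <- igraph::add_edges(g, t(edges))
  }
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) stop("duplicate edges are not allowed")
  igraph::V(g)$name <- if (is.null(node_ids)) as.character(seq_len(n)) else node_ids
  igraph::V(g)$r <- radial
  igraph::V(g)$theta <- angular
  g$disc_radius <- disc_radius
  g
}

# internal: validate that a graph carries the hyperbolic embedding
assert_embedded <- function(g) {
  if (!igraph::is_igraph(g)) stop("`network` must be an igraph object")
  va <- igraph::vertex_attr_names(g)
  if (!all(c("r", "theta") %in% va))
    stop("network has no hyperbolic coordinates (vertex attributes `r`, `theta`)")
  invisible(g)
}

# internal: 0-based CSR adjacency for the compiled kernels
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  ord <- order(from, to)
  deg <- tabulate(from, nbins = n)
  list(ptr = c(0L, cumsum(deg)), nbr = as.integer(to[ord] - 1L), n = n)
}

#' Generate a hyperbolic random graph
#'
#' Samples node coordinates via [sample_coordinates()] and connects every
#' unordered pair independently with [connection_probability()] of its
#' hyperbolic distance. The resulting graphs are scale-free with
#' degree-distribution exponent `gamma`, have mean degree close to
#' `kbar_target`, and a mean local clustering coefficient that decreases
#' with the temperature.
#'
#' Generation enumerates all `N (N - 1) / 2` pairs exactly (no candidate
#' pruning), which is practical for `N` up to a few tens of thousands.
#'
#' @param params a [network_params()] object. If `params$seed` is non-`NULL`
#'   the RNG is seeded with it; otherwise the current stream is used.
#' @return an embedded network (see [embedded_network()]).
#' @export
#' @examples
#' g <- generate_network(network_params(300, 2.6, 6, 0.3, seed = 1))
#' mean(igraph::degree(g))
generate_network <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (is.na(params$temperature))
    stop("`temperature` is NA; set it or calibrate it first")
  if (!is.null(params$seed)) set.seed(params$seed)
  R <- disc_radius(params)
  coords <- sample_coordinates(params, R)
  el <- sample_edges_core(coords$radial, coords$angular, R, params$temperature)
  embedded_network(el, coords$radial, coords$angular, R)
}

#' Extract the giant connected component
#'
#' Returns the induced subgraph on the largest connected node set, with all
#' coordinates preserved. Ties between equally large components are broken in
#' favour of the component containing the smallest node index. All game
#' dynamics in this package are run on the giant component only.
#'
#' @param network an igraph object (typically an embedded network).
#' @return the induced subgraph on the giant component.
#' @export
giant_component <- function(network) {
  if (!igraph::is_igraph(network)) stop("`network` must be an igraph object")
  if (igraph::vcount(network) == 0) stop("cannot take the giant component of an empty graph")
  comp <- igraph::components(network)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
    best <- best[which.min(first_member)]
  }
  igraph::induced_subgraph(network, which(comp$membership == best))
}

#' Mean local clustering coefficient
#'
#' The local clustering coefficient of a node with degree `k > 1` is
#' `c_i = 2 * (number of closed triangles through i) / (k_i * (k_i - 1))`;
#' the mean is taken over all nodes with degree greater than 1 (degree-1
#' nodes cannot close a triangle).
#'
#' @param network an igraph object.
#' @return the mean local clustering coefficient in `[0, 1]`.
#' @export
mean_local_clustering <- function(network) {
  if (!igraph::is_igraph(network)) stop("`network` must be an igraph object")
  deg <- igraph::degree(network)
  keep <- deg > 1
  if (!any(keep))
    stop("mean local clustering is undefined: no node has degree > 1")
  ci <- igraph::transitivity(network, type = "local", isolates = "zero")
  mean(ci[keep])
}

#' Degree statistics of a network
#'
#' Mean degree `2 |E| / N` and a maximum-likelihood estimate of the
#' power-law tail exponent of the degree distribution, using the standard
#' discrete Hill estimator `1 + n / sum(log(k / (k_min - 1/2)))` over
#' degrees `k >= k_min`. The exponent is a diagnostic; it is `NA` with a
#' warning when fewer than `min_tail` degrees reach `k_min` or when the tail
#' is degenerate (all equal).
#'
#' @param network an igraph object.
#' @param k_min smallest degree included in the tail fit (default 5).
#' @param min_tail minimum number of tail observations required (default 10).
#' @return a list with `mean_degree`, `tail_exponent`, `k_min`, `n_tail`.
#' @export
degree_sequence_stats <- function(network, k_min = 5, min_tail = 10) {
  if (!igraph::is_igraph(network) || igraph::vcount(network) == 0)
    stop("`network` must be a nonempty igraph object")
  deg <- igraph::degree(network)
  tail_deg <- deg[deg >= k_min]
  exponent <- NA_real_
  if (length(tail_deg) < min_tail || length(unique(tail_deg)) < 2) {
    warning("insufficient degree tail above k_min for a power-law fit")
  } else {
    exponent <- 1 + length(tail_deg) / sum(log(tail_deg / (k_min - 0.5)))
  }
  list(mean_degree = mean(deg), tail_exponent = exponent,
       k_min = k_min, n_tail = length(tail_deg))
}

#' Calibrate the graph temperature to a target mean local clustering
#'
#' The mean local clustering of generated networks decreases monotonically
#' (on average) with the temperature. This inverts that map numerically:
#' bisection on the temperature, measuring the clustering as the mean over
#' `pilot_realizations` generated networks per probe, until the measured
#' value is within `tol` of the target. Probe evaluations are cached per
#' `(N, gamma, kbar, pilot_realizations)` so repeated calibrations in a
#' session reuse earlier measurements.
#'
#' @param target_clustering desired mean local clustering in (0, 1).
#' @param params a [network_params()] object (its `temperature` is ignored).
#' @param pilot_realizations networks generated per probe (default 3).
#' @param tol calibration tolerance on the clustering (default 0.02).
#' @param t_range temperatures bracketing the search (default `c(0.05, 0.95)`).
#' @param max_iter maximum bisection steps (default 12).
#' @return the calibrated temperature.
#' @export
calibrate_temperature <- function(target_clustering, params,
                                  pilot_realizations = 3, tol = 0.02,
                                  t_range = c(0.05, 0.95), max_iter = 12) {
  stopifnot(inherits(params, "network_params"))
  if (target_clustering <= 0 || target_clustering >= 1)
    stop("`target_clustering` must lie in (0, 1)")
  base_key <- sprintf("N%d_g%.6g_k%.6g_p%d", params$n_nodes, params$gamma,
                      params$kbar_target, pilot_realizations)
  measure <- function(tt) {
    key <- sprintf("%s_T%.8f", base_key, tt)
    if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
    p <- params
    p$temperature <- tt
    p$seed <- NULL
    cs <- vapply(seq_len(pilot_realizations), function(i)
      mean_local_clustering(giant_component(generate_network(p))), 1.0)
    .calib_cache[[key]] <- mean(cs)
    mean(cs)
  }
  c_lo <- measure(t_range[1]) # highest achievable clustering
  c_hi <- measure(t_range[2]) # lowest
  if (target_clustering > c_lo + tol || target_clustering < c_hi - tol)
    stop(sprintf(
      "target clustering %.3f outside the achievable range [%.3f, %.3f] for these parameters",
      target_clustering, c_hi, c_lo))
  lo <- t_range[1]; hi <- t_range[2]
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cm <- measure(mid)
    if (abs(cm - target_clustering) <= tol) return(mid)
    if (cm > target_clustering) lo <- mid else hi <- mid
  }
  warning(sprintf("calibration stopped after %d bisection steps; returning best temperature %.4f",
                  max_iter, mid))
  mid
}
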