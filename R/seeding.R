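#' Random initial cooperators
#'
#' Each node independently becomes a cooperator with probability `density`.
#' The realised number of cooperators is binomial (exact in expectation only).
#'
#' @param network an igraph object.
#' @param density initial cooperation density `c(0)`; default 0.5.
#' @return a [strategy_state()].
#' @export
seed_random <- function(network, density = 0.5) {
  n <- igraph::vcount(network)
  strategy_state(runif(n) < density)
}

#' Degree-preferential (hub) initial cooperators
#'
#' Exactly `floor(density * N)` cooperators are drawn without replacement,
#' each successive draw with probability proportional to degree among the
#' remaining nodes, so high-degree hubs are strongly over-represented among
#' the initial cooperators.
#'
#' @inheritParams seed_random
#' @return a [strategy_state()].
#' @export
seed_hubs <- function(network, density = 0.5) {
  n <- igraph::vcount(network)
  m <- floor(density * n)
  s <- rep(FALSE, n)
  if (m >= n) return(strategy_state(rep(TRUE, n)))
  if (m > 0) {
    deg <- igraph::degree(network)
    s[sample.int(n, m, replace = FALSE, prob = deg)] <- TRUE
  }
  strategy_state(s)
}

# internal: node order along the angular coordinate, ties broken by index
theta_order <- function(network) {
  assert_embedded(network)
  order(igraph::V(network)$theta, seq_len(igraph::vcount(network)))
}

#' Metric-cluster initial cooperators
#'
#' Deterministic: nodes are sorted by their angular (similarity) coordinate
#' and the first `floor(density * N)` become cooperators, so the initial
#' cooperators occupy a single contiguous arc of the similarity circle.
#'
#' @inheritParams seed_random
#' @return a [strategy_state()].
#' @export
seed_metric_cluster <- function(network, density = 0.5) {
  ord <- theta_order(network)
  n <- length(ord)
  s <- rep(FALSE, n)
  s[ord[seq_len(floor(density * n))]] <- TRUE
  strategy_state(s)
}

#' Multiple metric clusters of initial cooperators
#'
#' Nodes sorted by angular coordinate are partitioned into `2 * n_clusters`
#' consecutive blocks of `floor(N / (2 * n_clusters))` nodes (any remainder
#' joins the final block), assigned alternately cooperator, defector,
#' cooperator, ... — yielding `n_clusters` disjoint cooperator arcs at total
#' density close to `density` (exactly `density = 0.5` block bookkeeping).
#'
#' @inheritParams seed_random
#' @param n_clusters number of disjoint cooperator clusters.
#' @return a [strategy_state()].
#' @export
seed_multiple_clusters <- function(network, density = 0.5, n_clusters) {
  ord <- theta_order(network)
  n <- length(ord)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1) stop("`n_clusters` must be >= 1")
  n_blocks <- 2L * n_clusters
  if (n_blocks > n)
    stop(sprintf("2 * n_clusters = %d exceeds the number of nodes (%d)", n_blocks, n))
  block_size <- floor(n / n_blocks)
  block <- pmin((seq_len(n) - 1L) %/% block_size, n_blocks - 1L)
  s <- rep(FALSE, n)
  s[ord[block %% 2L == 0L]] <- TRUE
  strategy_state(s)
}

#' Connected-cluster initial cooperators
#'
#' Nodes are removed from a working copy of the graph in uniform-random
#' order until the size of its giant connected component first reaches (or
#' drops below) `cluster_size`; the members of that component are then
#' assigned as cooperators in the original graph and everyone else defects.
#' The cooperator set always induces a connected subgraph, with no
#' constraint on its coordinates.
#'
#' A single removal can fragment the component and overshoot the target, so
#' the rule is "first time at or below `cluster_size`"; the achieved size is
#' attached as attribute `achieved_size`. The sequential removal is realised
#' as a binary search over prefixes of one uniform-random node permutation,
#' which is equivalent in distribution and much faster.
#'
#' @param network an igraph object.
#' @param cluster_size target number of cooperators (e.g. `N/2` or `N/4`).
#' @return a [strategy_state()] with attribute `achieved_size`.
#' @export
seed_connected_cluster <- function(network, cluster_size) {
  n <- igraph::vcount(network)
  if (cluster_size > n) stop("`cluster_size` exceeds the number of nodes")
  gcc_members <- function(removed) {
    h <- if (length(removed)) igraph::delete_vertices(network, removed) else network
    comp <- igraph::components(h)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1) {
      fm <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
      best <- best[which.min(fm)]
    }
    keep <- setdiff(seq_len(n), removed)
    keep[comp$membership == best]
  }
  perm <- sample.int(n)
  members0 <- gcc_members(integer(0))
  if (length(members0) <= cluster_size) {
    s <- rep(FALSE, n); s[members0] <- TRUE
    out <- strategy_state(s)
    attr(out, "achieved_size") <- length(members0)
    return(out)
  }
  # GCC size is non-increasing in the removal prefix: binary search for the
  # smallest prefix whose GCC is at or below the target
  lo <- 0L; hi <- n # gcc(lo) > target, gcc(hi) <= target (empty graph)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (length(gcc_members(perm[seq_len(mid)])) <= cluster_size) hi <- mid else lo <- mid
  }
  members <- gcc_members(perm[seq_len(hi)])
  s <- rep(FALSE, n); s[members] <- TRUE
  out <- strategy_state(s)
  attr(out, "achieved_size") <- length(members)
  out
}

#' Apply a seeding specification
#'
#' Dispatches a [seed_spec()] to the matching seeding procedure.
#'
#' @param network an igraph object.
#' @param spec a [seed_spec()].
#' @return a [strategy_state()].
#' @export
apply_seeding <- function(network, spec) {
  stopifnot(inherits(spec, "seed_spec"))
  switch(spec$scheme,
    random = seed_random(network, spec$density),
    hubs = seed_hubs(network, spec$density),
    metric_cluster = seed_metric_cluster(network, spec$density),
    multiple_metric_clusters =
      seed_multiple_clusters(network, spec$density, spec$n_clusters),
    connected_cluster = {
      size <- spec$cluster_size
      if (is.null(size)) size <- floor(spec$density * igraph::vcount(network))
      seed_connected_cluster(network, size)
    })
}
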