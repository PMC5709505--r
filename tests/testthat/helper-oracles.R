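# Brute-force oracles and small fixture builders used across the test files.

# mean local clustering by explicit per-node triangle enumeration
bf_mean_local_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  ci <- rep(NA_real_, nrow(A))
  for (i in seq_len(nrow(A))) {
    if (deg[i] < 2) next
    nb <- which(A[i, ] > 0)
    tri <- sum(A[nb, nb]) / 2
    ci[i] <- 2 * tri / (deg[i] * (deg[i] - 1))
  }
  mean(ci[deg > 1])
}

# per-node payoffs by a naive per-edge double loop
bf_payoffs <- function(g, s, params) {
  el <- igraph::as_edgelist(g, names = FALSE)
  pay <- numeric(igraph::vcount(g))
  one <- function(me, other) {
    if (me && other) 1
    else if (me && !other) params$sucker
    else if (!me && other) params$temptation
    else 0
  }
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    pay[i] <- pay[i] + one(s[i], s[j])
    pay[j] <- pay[j] + one(s[j], s[i])
  }
  pay
}

# KS distance from uniform on [0, 2*pi) by dense-grid sup evaluation
bf_ks_uniform_grid <- function(theta, n_grid = 1e5) {
  if (length(theta) == 0) return(0)
  grid <- seq(0, 2 * pi, length.out = n_grid)
  cdf <- stats::ecdf(theta)
  max(abs(cdf(grid) - grid / (2 * pi)))
}

# small random connected-ish test graph
random_test_graph <- function(n = 30, p = 0.15) {
  igraph::sample_gnp(n, p)
}

# an embedded network with prescribed angles (radii arbitrary), ring edges
# by default so every node has neighbours
embedded_fixture <- function(theta, edges = NULL, disc_radius = 10) {
  n <- length(theta)
  if (is.null(edges)) {
    edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  }
  embedded_network(edges, radial = rep(disc_radius / 2, n),
                   angular = theta, disc_radius = disc_radius)
}

# mirrors the package's documented child-seed derivation (root seed ->
# sample.int draws) for cross-checking experiment plumbing
derive_seeds_for_test <- function(root_seed, n) {
  withr::with_seed(as.integer(root_seed), sample.int(.Machine$integer.max, n))
}
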