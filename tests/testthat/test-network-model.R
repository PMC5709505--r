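test_that("disc radius matches the closed form and its scaling law", {
  np <- network_params(2000, gamma = 2.6, kbar_target = 6, temperature = 0.3)
  expect_equal(disc_radius(np), 14.9438224561437, tolerance = 1e-12)
  np2 <- network_params(4000, gamma = 2.6, kbar_target = 6, temperature = 0.3)
  expect_equal(disc_radius(np2) - disc_radius(np), 2 * log(2), tolerance = 1e-12)
  expect_true(disc_radius(network_params(5000, 2.6, 6, 0.3)) > disc_radius(np))
})

test_that("out-of-range model parameters are rejected by name", {
  expect_error(network_params(2000, gamma = 2, kbar_target = 6, temperature = 0.3),
               "gamma")
  expect_error(network_params(2000, gamma = 1.9, kbar_target = 6, temperature = 0.3),
               "gamma")
  expect_error(network_params(2000, gamma = 2.6, kbar_target = 6, temperature = 0),
               "temperature")
  expect_error(network_params(2000, gamma = 2.6, kbar_target = 6, temperature = 1),
               "temperature")
  expect_error(network_params(1, gamma = 2.6, kbar_target = 6, temperature = 0.3),
               "n_nodes")
})

test_that("radial sampler follows the truncated exponential-like density", {
  np <- network_params(1e5, gamma = 2.6, kbar_target = 6, temperature = 0.3)
  R <- 14.9438224561437
  set.seed(42)
  xy <- sample_coordinates(np, R)
  expect_true(all(xy$radial >= 0 & xy$radial <= R))
  expect_true(all(xy$angular >= 0 & xy$angular < 2 * pi))
  a <- (np$gamma - 1) / 2
  F <- function(r) (exp(a * (r - R)) - exp(-a * R)) / (1 - exp(-a * R))
  ks <- suppressWarnings(stats::ks.test(xy$radial, F))
  expect_lt(unname(ks$statistic), 0.01)
  med <- stats::uniroot(function(r) F(r) - 0.5, c(0, R), tol = 1e-10)$root
  expect_lt(abs(stats::median(xy$radial) - med) / med, 0.01)
  # angular coordinates uniform
  ks_th <- suppressWarnings(stats::ks.test(xy$angular / (2 * pi), "punif"))
  expect_lt(unname(ks_th$statistic), 0.01)
})

test_that("hyperbolic distance satisfies the metric reductions and stays stable", {
  expect_equal(hyperbolic_distance(3, 1.2, 3, 1.2), 0)
  expect_equal(hyperbolic_distance(3, 1.2, 7, 1.2), 4, tolerance = 1e-9)
  # symmetry on random points
  set.seed(1)
  r <- runif(50, 0, 30); th <- runif(50, 0, 2 * pi)
  d1 <- hyperbolic_distance(r[1:25], th[1:25], r[26:50], th[26:50])
  d2 <- hyperbolic_distance(r[26:50], th[26:50], r[1:25], th[1:25])
  expect_equal(d1, d2, tolerance = 1e-12)
  # frozen value at moderate radii (exact and asymptotic forms agree here)
  expect_equal(hyperbolic_distance(20, 0, 20, pi / 2), 39.3068528194401,
               tolerance = 1e-9)
  # very large radii take the asymptotic branch without overflow
  expect_equal(hyperbolic_distance(400, 0, 400, pi / 2), 800 - log(2),
               tolerance = 1e-9)
  # asymptotic branch is clipped below at |r1 - r2|
  expect_gte(hyperbolic_distance(500, 0, 100, 1e-12), 400)
})

test_that("connection probability is the Fermi-Dirac sigmoid in distance", {
  R <- 14.9
  expect_equal(connection_probability(R, R, 0.3), 0.5)
  expect_equal(connection_probability(R - 2 * 0.3, R, 0.3), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_lt(connection_probability(1e4, R, 0.3), 1e-10)
  expect_gt(connection_probability(0, 40, 0.3), 1 - 1e-10)
  x <- seq(0, 30, by = 0.5)
  expect_true(all(diff(connection_probability(x, R, 0.5)) < 0))
  expect_error(connection_probability(1, R, 1.2), "temperature")
})

test_that("two nodes at distance far below R are always linked", {
  el <- hypercoop:::sample_edges_core(c(0.1, 0.1), c(0, 0), 20, 0.2)
  expect_equal(nrow(el), 1L)
})

test_that("generated graphs are simple, carry coordinates, and hit the target degree", {
  gs <- lapply(1:5, function(s)
    generate_network(network_params(2000, 2.6, 6, 0.3, seed = s)))
  for (g in gs) {
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
    expect_length(igraph::V(g)$r, 2000)
    expect_length(igraph::V(g)$theta, 2000)
    expect_true(all(igraph::V(g)$r <= g$disc_radius))
  }
  kbar <- mean(vapply(gs, function(g) mean(igraph::degree(g)), 1.0))
  expect_lt(abs(kbar - 6) / 6, 0.15)
})

test_that("mean local clustering decreases with the graph temperature", {
  temps <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cbar <- vapply(temps, function(tt) {
    mean(vapply(1:3, function(s)
      mean_local_clustering(generate_network(network_params(1000, 2.6, 6, tt,
                                                            seed = s))), 1.0))
  }, 1.0)
  expect_true(all(diff(cbar) < 0))
})

test_that("giant component extraction preserves coordinates and breaks ties by node id", {
  # connected graph is returned whole
  g <- embedded_fixture(seq(0, 2 * pi - 0.1, length.out = 10))
  expect_equal(igraph::vcount(giant_component(g)), 10)
  # components of size 5 and 3
  edges <- rbind(cbind(1:4, 2:5), cbind(6:7, 7:8))
  g2 <- embedded_network(edges, radial = rep(1, 8),
                         angular = seq(0, 2, length.out = 8), disc_radius = 5)
  gc2 <- giant_component(g2)
  expect_equal(sort(igraph::V(gc2)$name), as.character(1:5))
  expect_equal(igraph::V(gc2)$theta,
               seq(0, 2, length.out = 8)[1:5])
  # two equal components: the one holding the smallest node id wins
  edges3 <- rbind(cbind(c(1, 2), c(2, 3)), cbind(c(4, 5), c(5, 6)))
  g3 <- embedded_network(edges3, radial = rep(1, 6),
                         angular = rep(0.5, 6), disc_radius = 5)
  expect_equal(sort(igraph::V(giant_component(g3))$name), as.character(1:3))
  expect_error(giant_component(igraph::make_empty_graph(0)), "empty")
})

test_that("mean local clustering matches hand values and the brute-force oracle", {
  tri <- igraph::make_full_graph(3)
  expect_equal(mean_local_clustering(tri), 1.0)
  star <- igraph::make_star(8, mode = "undirected")
  expect_equal(mean_local_clustering(star), 0.0) # hub only; no triangles
  chord <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 1, 1, 3), directed = FALSE)
  expect_equal(mean_local_clustering(chord), 5 / 6, tolerance = 1e-12)
  expect_error(mean_local_clustering(igraph::make_graph(c(1, 2), directed = FALSE)),
               "degree")
  set.seed(99)
  for (i in 1:20) {
    g <- random_test_graph(n = sample(5:50, 1))
    if (max(igraph::degree(g)) < 2) next
    expect_equal(mean_local_clustering(g), bf_mean_local_clustering(g),
                 tolerance = 1e-12)
  }
})

test_that("degree statistics report the mean degree and a tail exponent diagnostic", {
  ring3 <- igraph::make_ring(3)
  expect_equal(suppressWarnings(degree_sequence_stats(ring3))$mean_degree, 2)
  expect_warning(degree_sequence_stats(igraph::make_ring(30)), "tail")
  g <- generate_network(network_params(2000, 2.6, 6, 0.3, seed = 7))
  st <- degree_sequence_stats(g)
  expect_equal(st$mean_degree, 2 * igraph::ecount(g) / 2000)
  expect_gt(st$tail_exponent, 2)
  expect_lt(st$tail_exponent, 4.5)
})

test_that("temperature calibration inverts the clustering map and reports unachievable targets", {
  expect_error(
    calibrate_temperature(0.999, network_params(500, 2.6, 6)),
    "achievable")
  set.seed(21)
  tt <- calibrate_temperature(0.45, network_params(800, 2.6, 6),
                              pilot_realizations = 2, tol = 0.03)
  expect_true(tt > 0 && tt < 1)
  cbar <- mean(vapply(1:3, function(s)
    mean_local_clustering(generate_network(network_params(800, 2.6, 6, tt,
                                                          seed = s))), 1.0))
  expect_lt(abs(cbar - 0.45), 0.06)
})
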