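test_that("pair payoffs implement the R=1, P=0 normalised payoff matrix", {
  gp <- game_params(1.5, -0.5)
  expect_equal(pair_payoffs(TRUE, TRUE, gp), cbind(a = 1, b = 1))
  expect_equal(pair_payoffs(FALSE, FALSE, gp), cbind(a = 0, b = 0))
  gp2 <- game_params(1.2, -0.2)
  expect_equal(pair_payoffs(TRUE, FALSE, gp2), cbind(a = -0.2, b = 1.2))
  expect_equal(pair_payoffs(FALSE, TRUE, gp2), cbind(a = 1.2, b = -0.2))
  expect_error(game_params(1.2, -0.2, noise = 0), "noise")
})

test_that("round payoffs sum the per-neighbour games", {
  gp <- game_params(1.5, -0.5)
  g <- igraph::make_ring(6)
  expect_equal(accumulate_payoffs(g, rep(TRUE, 6), gp), igraph::degree(g))
  expect_equal(accumulate_payoffs(g, rep(FALSE, 6), gp), rep(0, 6))
  # D - C - D path: centre cooperator is exploited twice
  path <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(accumulate_payoffs(path, c(FALSE, TRUE, FALSE), gp),
               c(1.5, -1.0, 1.5))
})

test_that("round payoffs equal the per-edge brute-force oracle on random graphs", {
  set.seed(7)
  for (i in 1:20) {
    g <- random_test_graph(n = sample(5:50, 1))
    s <- runif(igraph::vcount(g)) < 0.5
    gp <- game_params(runif(1, 0, 2), runif(1, -1, 1))
    expect_equal(accumulate_payoffs(g, s, gp), bf_payoffs(g, s, gp),
                 tolerance = 1e-12)
  }
})

test_that("the Fermi imitation probability is a symmetric sigmoid in the payoff gap", {
  expect_equal(imitation_probability(1, 1, 0.5), 0.5)
  expect_equal(imitation_probability(0, 1, 0.5), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_lt(imitation_probability(1e4, 0, 0.5), 1e-10)
  set.seed(3)
  d <- rnorm(200, sd = 3)
  expect_equal(imitation_probability(0, d, 0.5) + imitation_probability(d, 0, 0.5),
               rep(1, 200), tolerance = 1e-12)
  expect_error(imitation_probability(0, 1, 0), "noise")
})

test_that("synchronous updates fix absorbing states and reject isolated nodes", {
  g <- igraph::make_ring(10)
  gp <- game_params(1.5, -0.5)
  allc <- strategy_state(rep(TRUE, 10),
                         accumulate_payoffs(g, rep(TRUE, 10), gp))
  stepped <- synchronous_step(g, allc, gp)
  expect_equal(stepped$strategy, rep(TRUE, 10))
  expect_equal(stepped$payoff, rep(0, 10)) # payoffs reset after the update
  g_iso <- igraph::add_vertices(g, 1)
  expect_error(synchronous_step(g_iso, strategy_state(rep(TRUE, 11)), gp),
               "neighbours")
})

test_that("with equal payoffs each node flips with probability one half", {
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  gp <- game_params(0.5, 0.5) # C and D earn the same against each other
  init <- strategy_state(c(TRUE, FALSE),
                         accumulate_payoffs(g2, c(TRUE, FALSE), gp))
  expect_equal(init$payoff, c(0.5, 0.5))
  set.seed(123)
  flips <- vapply(1:1e4, function(i)
    synchronous_step(g2, init, gp)$strategy[1] != init$strategy[1], TRUE)
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})

test_that("vanishing noise makes imitation of a richer neighbour deterministic", {
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  gp <- game_params(1.5, -0.5, noise = 1e-9)
  state <- strategy_state(c(TRUE, FALSE), payoff = c(-0.5, 1.5))
  set.seed(5)
  out <- synchronous_step(g2, state, gp)
  expect_equal(out$strategy, c(FALSE, FALSE))
})

test_that("simulations absorb, pad, stay in [0,1], and are bit-reproducible", {
  g <- giant_component(generate_network(network_params(300, 2.6, 6, 0.3, seed = 2)))
  gp <- game_params(1.5, -0.5)
  # all-cooperator initial state is absorbing from generation 0
  tr <- run_simulation(g, rep(TRUE, igraph::vcount(g)), gp, 50)
  expect_equal(tr$coop_density, rep(1, 51))
  expect_equal(tr$absorbed_at, 0L)
  # generic run: densities bounded, padding constant after absorption
  set.seed(8)
  tr2 <- run_simulation(g, seed_random(g, 0.5), gp, 300)
  expect_true(all(tr2$coop_density >= 0 & tr2$coop_density <= 1))
  if (!is.na(tr2$absorbed_at)) {
    after <- tr2$coop_density[(tr2$absorbed_at + 1):301]
    expect_true(all(after == after[1]))
  }
  set.seed(77)
  a <- run_simulation(g, seed_random(g, 0.5), gp, 100)
  set.seed(77)
  b <- run_simulation(g, seed_random(g, 0.5), gp, 100)
  expect_identical(a$coop_density, b$coop_density)
  expect_identical(a$final_strategy, b$final_strategy)
})

test_that("cooperation dominates the harmony game", {
  gp <- game_params(0.5, 0.5)
  wins <- 0
  for (i in 1:20) {
    set.seed(400 + i)
    g <- giant_component(generate_network(network_params(300, 2.7, 6, 0.4)))
    tr <- run_simulation(g, seed_random(g, 0.5), gp, 300)
    wins <- wins + (final_density(tr) == 1)
  }
  expect_gte(wins, 19) # >= 95% of runs reach full cooperation
})

test_that("trajectory recorders return KS and bin series on the schedule", {
  g <- giant_component(generate_network(network_params(400, 2.6, 6, 0.3, seed = 3)))
  gp <- game_params(1.2, -0.2)
  set.seed(10)
  tr <- run_simulation(g, seed_random(g, 0.5), gp, 60,
                       record_ks = TRUE, record_bins = TRUE, n_bins = 12,
                       schedule = c(10, 30, 60))
  expect_equal(tr$ks$generation, c(10, 30, 60))
  expect_equal(dim(tr$bins), c(3, 12))
  # the weighted decomposition holds on every recorded row
  expect_true(all(tr$ks$rho_bar >= 0 & tr$ks$rho_bar <= 1))
  # final-generation KS from the recorder agrees with a direct computation
  direct <- ks_statistic(g, tr$final_strategy)
  expect_equal(tr$ks$rho_bar[3], direct$rho_bar, tolerance = 1e-12)
})
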