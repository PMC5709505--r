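#' Strategy state of the population
#'
#' A per-node binary strategy vector (`TRUE` = cooperate, `FALSE` = defect)
#' together with the payoffs accumulated in the current round.
#'
#' @param strategy logical vector of strategies.
#' @param payoff numeric vector of per-node round payoffs; defaults to zeros.
#' @return an object of class `strategy_state`.
#' @export
strategy_state <- function(strategy, payoff = numeric(length(strategy))) {
  strategy <- as.logical(strategy)
  if (anyNA(strategy)) stop("strategies must be TRUE/FALSE with no NA")
  if (length(payoff) != length(strategy))
    stop("`payoff` must have one entry per node")
  structure(list(strategy = strategy, payoff = as.numeric(payoff)),
            class = "strategy_state")
}

#' @export
print.strategy_state <- function(x, ...) {
  cat(sprintf("Strategy state: %d nodes, cooperation density %.4f\n",
              length(x$strategy), mean(x$strategy)))
  invisible(x)
}

# internal: accept a strategy_state or a plain logical vector
as_strategy <- function(x, n = NULL) {
  s <- if (inherits(x, "strategy_state")) x$strategy else as.logical(x)
  if (anyNA(s)) stop("strategies must be TRUE/FALSE with no NA")
  if (!is.null(n) && length(s) != n)
    stop("strategy vector length does not match the number of nodes")
  s
}

#' Payoffs of a single two-player game
#'
#' With the normalisation reward = 1 (mutual cooperation) and punishment = 0
#' (mutual defection): (C,C) pays (1,1); (C,D) pays (S, T); (D,C) pays
#' (T, S); (D,D) pays (0,0). Vectorised over strategy pairs.
#'
#' @param strategy_a,strategy_b logical; `TRUE` = cooperate.
#' @param params a [game_params()] object.
#' @return a two-column numeric matrix with columns `a` and `b`.
#' @export
#' @examples
#' pair_payoffs(TRUE, FALSE, game_params(1.2, -0.2))
pair_payoffs <- function(strategy_a, strategy_b, params) {
  stopifnot(inherits(params, "game_params"))
  a <- as.logical(strategy_a); b <- as.logical(strategy_b)
  pa <- ifelse(a, ifelse(b, 1, params$sucker), ifelse(b, params$temptation, 0))
  pb <- ifelse(b, ifelse(a, 1, params$sucker), ifelse(a, params$temptation, 0))
  cbind(a = pa, b = pb)
}

#' Accumulate round payoffs over the network
#'
#' One round consists of every node playing one game with each of its
#' neighbours; the round payoff of node `i` is the sum of its payoffs over
#' those games.
#'
#' @param network an igraph object.
#' @param strategies a [strategy_state()] or logical vector.
#' @param params a [game_params()] object.
#' @return numeric vector of per-node payoffs.
#' @export
accumulate_payoffs <- function(network, strategies, params) {
  stopifnot(inherits(params, "game_params"))
  csr <- graph_csr(network)
  s <- as_strategy(strategies, csr$n)
  payoffs_core(csr$ptr, csr$nbr, s, params$temptation, params$sucker)
}

#' Fermi imitation probability
#'
#' Probability that a focal player with round payoff `payoff_self` adopts
#' the strategy of a neighbour with payoff `payoff_neighbor`:
#' `P = 1 / (1 + exp(-(payoff_neighbor - payoff_self) / noise))`.
#' Satisfies `P(delta) + P(-delta) = 1`.
#'
#' @param payoff_self,payoff_neighbor numeric payoffs (recycled).
#' @param noise positive selection noise `K`.
#' @return probabilities in `[0, 1]`.
#' @export
imitation_probability <- function(payoff_self, payoff_neighbor, noise) {
  if (any(noise <= 0)) stop("`noise` (K) must be positive")
  plogis((payoff_neighbor - payoff_self) / noise)
}

#' One synchronous imitation update
#'
#' Every node independently picks one of its neighbours uniformly at random
#' and adopts that neighbour's current strategy with the Fermi
#' [imitation_probability()] computed from the supplied round payoffs. All
#' adoptions are applied simultaneously from the pre-update snapshot, and all
#' payoffs are reset to zero afterwards.
#'
#' The payoffs in `state` must be the accumulated payoffs of the current
#' round (see [accumulate_payoffs()]). Nodes without neighbours are an
#' error: the dynamics are defined on the giant component.
#'
#' @param network an igraph object.
#' @param state a [strategy_state()] whose `payoff` holds the current round
#'   payoffs.
#' @param params a [game_params()] object.
#' @return the post-update [strategy_state()] (payoffs zeroed).
#' @export
synchronous_step <- function(network, state, params) {
  stopifnot(inherits(state, "strategy_state"), inherits(params, "game_params"))
  csr <- graph_csr(network)
  n <- csr$n
  s <- as_strategy(state, n)
  k <- diff(csr$ptr)
  if (any(k == 0))
    stop("some nodes have no neighbours; run the dynamics on the giant component")
  pay <- state$payoff
  pick <- csr$ptr[seq_len(n)] + pmin(floor(runif(n) * k), k - 1)
  j <- csr$nbr[pick + 1L] + 1L
  adopt <- runif(n) < imitation_probability(pay, pay[j], params$noise)
  strategy_state(ifelse(adopt, s[j], s))
}

# internal: default recorder schedule — every generation up to 1000, then
# logarithmically spaced up to the horizon
default_schedule <- function(n_generations, dense_until = 1000L, n_log = 50L) {
  dense <- seq_len(min(n_generations, dense_until))
  if (n_generations <= dense_until) return(dense)
  logs <- unique(round(exp(seq(log(dense_until), log(n_generations),
                               length.out = n_log))))
  sort(unique(c(dense, logs)))
}

#' Run the evolutionary game dynamics
#'
#' Iterates payoff accumulation and the synchronous Fermi imitation update
#' for `n_generations` generations, or until the population absorbs at full
#' cooperation or full defection (absorbing states are fixed points; by
#' default the loop then exits early and the remaining trajectory is padded
#' with the absorbing value).
#'
#' The cooperation density is recorded every generation. When
#' `record_ks`/`record_bins` is set, the angular KS statistic (see
#' [ks_statistic()]) and the binned angular cooperation profile (see
#' [angular_bins()]) are recorded at the generations in `schedule` (default:
#' every generation up to 1000, then logarithmically spaced).
#'
#' Uses the current R RNG stream: trajectories are bit-reproducible given
#' the network and `set.seed()`.
#'
#' @param network an igraph object; all nodes must have at least one
#'   neighbour (use [giant_component()]).
#' @param initial a [strategy_state()] or logical vector of initial
#'   strategies.
#' @param params a [game_params()] object.
#' @param n_generations number of synchronous generations.
#' @param record_ks record the angular KS statistic along the trajectory
#'   (requires coordinates on the network).
#' @param record_bins record binned angular cooperation densities.
#' @param n_bins number of angular bins (default 20).
#' @param schedule generations at which KS/bin recorders fire.
#' @param early_exit stop iterating once absorbed (results are identical to
#'   running the full horizon).
#' @return an object of class `trajectory`: a list with `generations`
#'   (0..n), `coop_density`, `absorbed_at` (`NA` if never absorbed),
#'   `final_strategy`, and optionally data frame `ks` and matrix `bins`
#'   (rows = recorded generations).
#' @export
run_simulation <- function(network, initial, params, n_generations,
                           record_ks = FALSE, record_bins = FALSE,
                           n_bins = 20, schedule = NULL, early_exit = TRUE) {
  stopifnot(inherits(params, "game_params"), n_generations >= 1)
  csr <- graph_csr(network)
  s0 <- as_strategy(initial, csr$n)
  want_snaps <- record_ks || record_bins
  if (want_snaps) assert_embedded(network)
  snap_at <- if (want_snaps) {
    if (is.null(schedule)) default_schedule(n_generations)
    else sort(unique(as.integer(schedule)))
  } else integer(0)
  res <- fermi_run_core(csr$ptr, csr$nbr, s0, params$temptation,
                        params$sucker, params$noise,
                        as.integer(n_generations), snap_at, early_exit)
  out <- list(generations = 0:n_generations,
              coop_density = res$density,
              absorbed_at = if (res$absorbed_at < 0) NA_integer_ else res$absorbed_at,
              final_strategy = res$final_strategy)
  if (record_ks) {
    ks <- lapply(seq_along(snap_at), function(i)
      ks_statistic(network, res$snapshots[i, ]))
    out$ks <- data.frame(generation = snap_at,
                         rho_c = vapply(ks, `[[`, 1.0, "rho_c"),
                         rho_d = vapply(ks, `[[`, 1.0, "rho_d"),
                         rho_bar = vapply(ks, `[[`, 1.0, "rho_bar"))
  }
  if (record_bins) {
    bins <- t(vapply(seq_along(snap_at), function(i)
      angular_bins(network, res$snapshots[i, ], n_bins)$coop_fraction,
      numeric(n_bins)))
    rownames(bins) <- snap_at
    out$bins <- bins
  }
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$coop_density) - 1L
  cat(sprintf("Trajectory: %d generations, C(0) = %.3f, final C = %.4f%s\n",
              n, x$coop_density[1], x$coop_density[n + 1L],
              if (is.na(x$absorbed_at)) ""
              else sprintf(", absorbed at generation %d", x$absorbed_at)))
  invisible(x)
}

#' Final cooperation density of a trajectory
#'
#' @param trajectory a `trajectory` from [run_simulation()].
#' @return the cooperation density at the final generation.
#' @export
final_density <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  tail(trajectory$coop_density, 1L)
}
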