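#' Control parameters for the coot optimizers
#'
#' Collects and validates the tunable parameters of [coot_optim()]. Defaults
#' follow common swarm-optimizer practice: a population of 30 agents, a tenth
#' of them designated group leaders, and a Levy exponent of 1.5.
#'
#' @param n_agents Population size \eqn{N} (default 30).
#' @param leader_frac Fraction of agents designated leaders; the number of
#'   leaders is \eqn{NL = \lceil \code{leader_frac} \cdot N \rceil}, at least
#'   one and strictly fewer than \eqn{N}.
#' @param max_iter Number of iterations \eqn{I_{max}} (default 100).
#' @param beta Levy-stable exponent \eqn{\beta \in (0, 2]} (default 1.5).
#' @param alpha Levy step scale multiplying each perturbation (default 1).
#' @param p_follow Probability that a follower moves toward its leader rather
#'   than performing chain or random movement.
#' @param p_chain Probability of chain movement (average with the previous
#'   agent) when not following a leader.
#' @param p_levy Per-agent probability of a Levy perturbation each iteration
#'   (improved variant only).
#' @param jumping_rate Per-iteration probability of a quasi-opposition pass
#'   over the whole population (improved variant only).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @param levy_mode `"additive"` (default) adds the scaled Levy step to the
#'   position; `"multiplicative"` multiplies the position entrywise by the
#'   step, the literal reading of the update rule.
#' @param levy_draws `"normal"` (default) draws the two Levy variates from the
#'   standard normal as Mantegna's method requires; `"uniform"` draws them
#'   uniformly on \[0, 1\].
#' @param r1_per_dim Logical; draw the random-movement mixing coefficient per
#'   dimension (default) or as a scalar.
#'
#' @return An object of class `"coot_control"`, a validated list.
#' @seealso [coot_optim()]
#' @examples
#' coot_control(n_agents = 20, max_iter = 50, seed = 1)
#' @export
coot_control <- function(n_agents = 30L, leader_frac = 0.1, max_iter = 100L,
                         beta = 1.5, alpha = 1.0,
                         p_follow = 0.5, p_chain = 0.5,
                         p_levy = 0.5, jumping_rate = 0.3,
                         seed = NULL,
                         levy_mode = c("additive", "multiplicative"),
                         levy_draws = c("normal", "uniform"),
                         r1_per_dim = TRUE) {
  if (!is_count(n_agents) || n_agents < 2)
    stop("'n_agents' must be an integer >= 2", call. = FALSE)
  if (!is_prob(leader_frac) || leader_frac <= 0)
    stop("'leader_frac' must be in (0, 1]", call. = FALSE)
  if (!is_count(max_iter)) stop("'max_iter' must be a positive integer", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 2)
    stop("'beta' must lie in (0, 2]", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a finite number", call. = FALSE)
  for (p in c(p_follow = p_follow, p_chain = p_chain,
              p_levy = p_levy, jumping_rate = jumping_rate))
    if (!is_prob(p)) stop("operator probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed) && !is_count(abs(seed) + 1))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  n_leaders <- max(1L, as.integer(ceiling(leader_frac * n_agents)))
  if (n_leaders >= n_agents)
    stop("the leader count must be smaller than 'n_agents'", call. = FALSE)
  structure(list(
    n_agents = as.integer(n_agents), leader_frac = leader_frac,
    n_leaders = n_leaders, max_iter = as.integer(max_iter),
    beta = beta, alpha = alpha,
    p_follow = p_follow, p_chain = p_chain,
    p_levy = p_levy, jumping_rate = jumping_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    levy_mode = match.arg(levy_mode),
    levy_draws = match.arg(levy_draws),
    r1_per_dim = isTRUE(r1_per_dim)
  ), class = "coot_control")
}

#' @export
print.coot_control <- function(x, ...) {
  cat("Coot optimizer control:\n")
  cat(sprintf("  agents: %d (%d leaders), iterations: %d\n",
              x$n_agents, x$n_leaders, x$max_iter))
  cat(sprintf("  p_follow = %.2f, p_chain = %.2f, p_levy = %.2f, jumping_rate = %.2f\n",
              x$p_follow, x$p_chain, x$p_levy, x$jumping_rate))
  cat(sprintf("  Levy: beta = %.2f, alpha = %.2f, %s, %s draws\n",
              x$beta, x$alpha, x$levy_mode, x$levy_draws))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
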