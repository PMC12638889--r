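#' Coot swarm optimization over a box-bounded continuous space
#'
#' Minimizes or maximizes an objective with the coot-bird swarm optimizer
#' (`algorithm = "coot"`) or its improved variant (`"icoot"`, the default)
#' that augments every iteration with a greedy Levy-flight perturbation pass
#' and, at a configurable jumping rate, a quasi-opposition-based learning pass
#' over the whole population.
#'
#' @section Algorithm:
#' The population of \eqn{N} agents is initialized uniformly in the box and,
#' after the initial evaluation, the \eqn{NL} fittest agents become group
#' leaders. Each iteration \eqn{t}:
#' \enumerate{
#'   \item the exploration coefficient \eqn{B = 1 - t/I_{max}} decays linearly;
#'   \item each follower, in index order, either follows its leader (with
#'     probability `p_follow`), performs chain movement with its predecessor
#'     (probability `p_chain` otherwise), or moves toward a random point of
#'     the box; updates are sequential, so chain movement sees already-moved
#'     predecessors;
#'   \item each leader moves around the global best;
#'   \item (`icoot` only) each agent is perturbed by a Levy step with
#'     probability `p_levy`, keeping the fitter of the pair;
#'   \item (`icoot` only) with probability `jumping_rate` a quasi-opposition
#'     pass replaces each agent by its quasi-opposite when fitter.
#' }
#' The best-so-far solution is retained elitistically; the convergence trace
#' is therefore monotone. With `p_levy = 0` and `jumping_rate = 0` the
#' improved variant consumes no extra random draws and reproduces the
#' baseline run exactly.
#'
#' @section Random draws:
#' A single seeded stream drives the run. Per follower: the follow/chain
#' gating uniforms, then either (`r2`, `r3`) for a leader follow, or the
#' random point plus mixing coefficient(s) for a random move. Per leader:
#' (`r3`, `r4`, `r5`). The improved passes draw one gating uniform per agent
#' (Levy) or per iteration (quasi-opposition) plus the step/point variates.
#'
#' @param fn Objective: a function of a numeric vector returning a finite
#'   scalar.
#' @param lower,upper Per-dimension bounds; recycled to a common length, which
#'   sets the problem dimension. Must satisfy `upper > lower`.
#' @param control A [coot_control()] object (population size, iterations,
#'   operator probabilities, seed, ...).
#' @param algorithm `"icoot"` (improved, default) or `"coot"` (baseline).
#' @param mode `"minimize"` (default) or `"maximize"`.
#'
#' @return An object of class `"coot_optim"`: a list with elements
#'   `par` (best position found), `value` (objective there), `trace`
#'   (best-so-far objective per iteration, length `max_iter`), `evaluations`
#'   (objective call count), plus the echoed `algorithm`, `mode`, `control`,
#'   and `bounds`.
#'
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- coot_optim(sphere, -100, 100, coot_control(max_iter = 50, seed = 1))
#' fit$value
#' \donttest{plot(fit)}
#' @seealso [coot_control()], [otsu_segment()] which drives this optimizer
#'   with the between-class-variance objective.
#' @export
coot_optim <- function(fn, lower, upper, control = coot_control(),
                       algorithm = c("icoot", "coot"),
                       mode = c("minimize", "maximize")) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (!inherits(control, "coot_control"))
    stop("'control' must be a coot_control() object", call. = FALSE)
  if (!is.function(fn)) stop("'fn' must be a function", call. = FALSE)
  d <- max(length(lower), length(upper))
  if (d < 1L) stop("bounds must have length >= 1", call. = FALSE)
  lb <- rep_len(as.numeric(lower), d)
  ub <- rep_len(as.numeric(upper), d)
  if (!all(is.finite(lb)) || !all(is.finite(ub)) || any(ub <= lb))
    stop("bounds must be finite with upper > lower in every dimension",
         call. = FALSE)

  with_seed(control$seed, coot_run(fn, lb, ub, control, algorithm, mode))
}

## The seeded optimization loop. Kept separate from the public wrapper so the
## RNG bracketing in coot_optim() stays trivial.
coot_run <- function(fn, lb, ub, control, algorithm, mode) {
  d <- length(lb)
  n <- control$n_agents
  nl <- control$n_leaders
  maximize <- mode == "maximize"
  n_eval <- 0L

  evaluate <- function(x, what) {
    n_eval <<- n_eval + 1L
    val <- fn(x)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("objective returned a non-finite value during %s at (%s)",
                   what, paste(signif(x, 6), collapse = ", ")), call. = FALSE)
    as.numeric(val)
  }
  better <- if (maximize) function(a, b) a > b else function(a, b) a < b

  ## --- initialization: uniform positions, fitness ranking, leader partition
  pop <- matrix(stats::runif(n * d), nrow = n, byrow = TRUE)
  pop <- sweep(sweep(pop, 2, ub - lb, `*`), 2, lb, `+`)
  fit <- vapply(seq_len(n), function(i) evaluate(pop[i, ], "initialization"),
                numeric(1))
  ord <- order(fit, decreasing = maximize)
  pop <- pop[ord, , drop = FALSE]
  fit <- fit[ord]
  gbest <- pop[1L, ]
  gbest_fit <- fit[1L]

  trace <- numeric(control$max_iter)

  accept <- function(i, cand, what) {
    cand_fit <- evaluate(cand, what)
    pop[i, ] <<- cand
    fit[i] <<- cand_fit
    if (better(cand_fit, gbest_fit)) {
      gbest <<- cand
      gbest_fit <<- cand_fit
    }
  }
  greedy_accept <- function(i, cand, what) {
    cand_fit <- evaluate(cand, what)
    if (better(cand_fit, fit[i])) {
      pop[i, ] <<- cand
      fit[i] <<- cand_fit
      if (better(cand_fit, gbest_fit)) {
        gbest <<- cand
        gbest_fit <<- cand_fit
      }
    }
  }

  for (t in seq_len(control$max_iter)) {
    b <- coot_decay(t, control$max_iter)

    ## follower movements (agents nl+1 .. n, sequential)
    for (i in seq.int(nl + 1L, n)) {
      if (stats::runif(1) < control$p_follow) {
        k <- coot_leader_index(i - nl - 1L, nl)
        r2 <- stats::runif(1)
        r3 <- stats::runif(1, -1, 1)
        cand <- coot_follow_move(pop[i, ], pop[k, ], r2, r3, lb, ub)
      } else if (stats::runif(1) < control$p_chain) {
        cand <- clamp_bounds(coot_chain_move(pop[i, ], pop[i - 1L, ]), lb, ub)
      } else {
        r_point <- stats::runif(d, lb, ub)
        r1 <- if (control$r1_per_dim) stats::runif(d) else stats::runif(1)
        cand <- coot_random_move(pop[i, ], b, r_point, r1, lb, ub)
      }
      accept(i, cand, "follower movement")
    }

    ## leader movements
    for (i in seq_len(nl)) {
      r3 <- stats::runif(1, -1, 1)
      r4 <- stats::runif(1)
      r5 <- stats::runif(1)
      cand <- coot_leader_move(pop[i, ], gbest, b, r3, r4, r5, lb, ub)
      accept(i, cand, "leader movement")
    }

    if (algorithm == "icoot") {
      ## Levy perturbation pass: greedy keep-fitter. When p_levy == 0 no
      ## draws are consumed, so the run reduces exactly to the baseline.
      if (control$p_levy > 0) {
        for (i in seq_len(n)) {
          if (stats::runif(1) < control$p_levy) {
            cand <- levy_perturb(pop[i, ], control$alpha, control$beta,
                                 lb, ub, mode = control$levy_mode,
                                 draws = control$levy_draws)
            greedy_accept(i, cand, "Levy perturbation")
          }
        }
      }
      ## quasi-opposition pass, gated per iteration
      if (control$jumping_rate > 0 &&
          stats::runif(1) < control$jumping_rate) {
        for (i in seq_len(n)) {
          cand <- quasi_opposite_point(pop[i, ], lb, ub)
          greedy_accept(i, cand, "quasi-opposition learning")
        }
      }
    }

    trace[t] <- gbest_fit
  }

  structure(list(par = gbest, value = gbest_fit, trace = trace,
                 evaluations = n_eval, algorithm = algorithm, mode = mode,
                 control = control, bounds = list(lower = lb, upper = ub)),
            class = "coot_optim")
}

#' @export
print.coot_optim <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat(sprintf("%s optimizer (%s), %d agents x %d iterations\n",
              toupper(x$algorithm), x$mode,
              x$control$n_agents, x$control$max_iter))
  cat("Best value: ", format(x$value, digits = digits), "\n", sep = "")
  cat("Best position:\n")
  print(signif(x$par, digits))
  invisible(x)
}

#' Plot the convergence trace of a coot optimizer run
#'
#' @param x A `"coot_optim"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.coot_optim <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "Iteration", ylab = "Best objective",
                 main = sprintf("%s convergence", toupper(x$algorithm)), ...)
  invisible(x)
}
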