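#' Movement operators of the coot optimizer
#'
#' The population update of [coot_optim()] is built from small pure functions,
#' exported so the algorithm's mechanics can be examined and unit-tested with
#' fixed random draws. All random quantities are passed in as arguments; the
#' optimizer itself draws them from a single seeded stream.
#'
#' * `coot_decay()` is the linear exploration coefficient
#'   \eqn{B = 1 - I_c / I_{max}}, decaying from 1 to 0 over the run.
#' * `coot_random_move()` moves a position toward a random point `r_point` of
#'   the search space: \eqn{x + B \, r_1 (R - x)}.
#' * `coot_chain_move()` is the entrywise mean of an agent and its predecessor.
#' * `coot_leader_index()` maps follower counter `j` to a 1-based leader label
#'   \eqn{K = 1 + (j \bmod NL)}.
#' * `coot_follow_move()` moves a follower around its leader:
#'   \eqn{L + 2 r_2 \cos(2\pi r_3)(L - x)}.
#' * `coot_leader_move()` moves a leader around the global best `gbest`:
#'   \eqn{B r_4 \cos(2\pi r_3)(g - L) + g} when \eqn{r_5 < 0.5}, and the same
#'   term minus \eqn{g} otherwise.
#'
#' Moves that can leave the search box are clamped to the nearest bound.
#'
#' @param current_iter,max_iter Iteration counter (0-based allowed) and total
#'   iteration count.
#' @param position,pos_prev,leader,gbest Numeric position vectors of equal
#'   length.
#' @param b Exploration coefficient, typically from `coot_decay()`.
#' @param r_point Random point of the search space (same length as `position`).
#' @param r1 Uniform draw(s) on \[0, 1\], scalar or per-dimension.
#' @param r2,r4,r5 Scalar uniform draws on \[0, 1\].
#' @param r3 Scalar uniform draw on \[-1, 1\].
#' @param j Follower counter (non-negative integer).
#' @param n_leaders Number of leaders (positive integer).
#' @param lb,ub Per-dimension lower/upper bounds (recycled).
#'
#' @return A numeric vector (a new position), except `coot_decay()` and
#'   `coot_leader_index()` which return scalars.
#' @examples
#' coot_decay(50, 100)                      # 0.5
#' coot_chain_move(c(2, 4), c(6, 8))        # c(4, 6)
#' coot_leader_index(5, 3)                  # 3
#' coot_follow_move(c(4), c(10), 0.5, 0, lb = -100, ub = 100)  # 16
#' @name coot_operators
NULL

#' @rdname coot_operators
#' @export
coot_decay <- function(current_iter, max_iter) {
  if (!is_count(max_iter)) stop("'max_iter' must be a positive integer", call. = FALSE)
  if (current_iter < 0 || current_iter > max_iter)
    stop("'current_iter' must lie in [0, max_iter]", call. = FALSE)
  1 - current_iter / max_iter
}

#' @rdname coot_operators
#' @export
coot_random_move <- function(position, b, r_point, r1, lb, ub) {
  clamp_bounds(position + b * r1 * (r_point - position), lb, ub)
}

#' @rdname coot_operators
#' @export
coot_chain_move <- function(position, pos_prev) {
  if (length(position) != length(pos_prev))
    stop("positions must have equal length", call. = FALSE)
  (position + pos_prev) / 2
}

#' @rdname coot_operators
#' @export
coot_leader_index <- function(j, n_leaders) {
  if (!is_count(n_leaders)) stop("'n_leaders' must be a positive integer", call. = FALSE)
  if (j < 0) stop("'j' must be non-negative", call. = FALSE)
  1L + (as.integer(j) %% as.integer(n_leaders))
}

#' @rdname coot_operators
#' @export
coot_follow_move <- function(position, leader, r2, r3, lb, ub) {
  if (length(position) != length(leader))
    stop("positions must have equal length", call. = FALSE)
  clamp_bounds(leader + 2 * r2 * cos(2 * pi * r3) * (leader - position), lb, ub)
}

#' @rdname coot_operators
#' @export
coot_leader_move <- function(leader, gbest, b, r3, r4, r5, lb, ub) {
  term <- b * r4 * cos(2 * pi * r3) * (gbest - leader)
  out <- if (r5 < 0.5) term + gbest else term - gbest
  clamp_bounds(out, lb, ub)
}

#' Levy-flight steps (Mantegna's method)
#'
#' `levy_sigma()` evaluates the Mantegna scale
#' \deqn{\sigma(\beta) = \left[\frac{\Gamma(1+\beta)\,\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta},}
#' and `levy_step()` draws a heavy-tailed step vector
#' \eqn{0.01\, u \sigma / |v|^{1/\beta}} per dimension, where `u` and `v` are
#' standard-normal by default (Mantegna's construction; a uniform mode exists
#' for comparison). `levy_perturb()` applies a step to a position, either
#' additively (default) or multiplicatively, then clamps to the bounds.
#'
#' @param beta Levy exponent in (0, 2].
#' @param dim Number of dimensions.
#' @param draws `"normal"` or `"uniform"` variates for the step ratio.
#' @param u,v Optional fixed variates (length `dim`) overriding the draws;
#'   used for reproducible unit evaluation.
#' @param position Numeric position vector.
#' @param alpha Step scale.
#' @param step Optional fixed step vector; drawn via `levy_step()` if missing.
#' @param mode `"additive"` or `"multiplicative"` application.
#' @param lb,ub Bounds (recycled).
#' @return `levy_sigma()` a scalar; the others numeric vectors.
#' @examples
#' levy_sigma(1.5)            # about 0.6966
#' set.seed(1); levy_step(3, 1.5)
#' @name levy_flight
NULL

#' @rdname levy_flight
#' @export
levy_sigma <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 2)
    stop("'beta' must lie in (0, 2]", call. = FALSE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' @rdname levy_flight
#' @export
levy_step <- function(dim, beta = 1.5, draws = c("normal", "uniform"),
                      u = NULL, v = NULL) {
  if (!is_count(dim)) stop("'dim' must be a positive integer", call. = FALSE)
  draws <- match.arg(draws)
  sig <- levy_sigma(beta)
  if (is.null(u)) u <- if (draws == "normal") stats::rnorm(dim) else stats::runif(dim)
  if (is.null(v)) v <- if (draws == "normal") stats::rnorm(dim) else stats::runif(dim)
  ## |v| = 0 has probability zero under the normal law; resample defensively
  while (any(v == 0))
    v[v == 0] <- if (draws == "normal") stats::rnorm(sum(v == 0)) else stats::runif(sum(v == 0))
  0.01 * u * sig / abs(v)^(1 / beta)
}

#' @rdname levy_flight
#' @export
levy_perturb <- function(position, alpha = 1, beta = 1.5, lb, ub,
                         mode = c("additive", "multiplicative"),
                         draws = c("normal", "uniform"), step = NULL) {
  mode <- match.arg(mode)
  if (is.null(step)) step <- levy_step(length(position), beta, match.arg(draws))
  out <- if (mode == "additive") position + alpha * step
         else position * (alpha * step)
  clamp_bounds(out, lb, ub)
}

#' Opposition and quasi-opposition points
#'
#' `opposite_point()` mirrors a position through the center of the search box,
#' \eqn{\tilde x = ub + lb - x}. `quasi_opposite_point()` draws, per dimension,
#' a uniform point between the box center \eqn{c = (ub+lb)/2} and the opposite
#' point, whichever order they fall in. Keeping the fitter of an agent and its
#' (quasi-)opposite is the opposition-based learning step of the improved
#' optimizer.
#'
#' @param position Numeric position vector inside the bounds.
#' @param lb,ub Bounds (recycled to the position length).
#' @param u Optional fixed uniform draws on \[0, 1\] (length of `position`)
#'   for reproducible evaluation.
#' @return A numeric vector of the same length as `position`.
#' @examples
#' opposite_point(200, 0, 255)        # 55
#' quasi_opposite_point(0.2, 0, 1, u = 0)  # 0.5 (the interval center)
#' @name opposition
NULL

#' @rdname opposition
#' @export
opposite_point <- function(position, lb, ub) {
  ub + lb - position
}

#' @rdname opposition
#' @export
quasi_opposite_point <- function(position, lb, ub, u = NULL) {
  centre <- (ub + lb) / 2
  opp <- opposite_point(position, lb, ub)
  lo <- pmin(centre, opp)
  hi <- pmax(centre, opp)
  if (is.null(u)) u <- stats::runif(length(position))
  lo + u * (hi - lo)
}
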