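# Unit laws of the movement operators, evaluated with fixed draws.

test_that("exploration coefficient decays linearly from 1 to 0", {
  expect_equal(coot_decay(0, 100), 1.0)
  expect_equal(coot_decay(100, 100), 0.0)
  expect_equal(coot_decay(50, 100), 0.5)
  expect_error(coot_decay(1, 0), "max_iter")
  expect_error(coot_decay(-1, 10), "current_iter")
})

test_that("random movement follows x + B*r1*(R - x) and clamps", {
  expect_equal(coot_random_move(c(3, 7), b = 0, r_point = c(50, 50),
                                r1 = 1, lb = 0, ub = 255), c(3, 7))
  expect_equal(coot_random_move(c(3, 7), b = 1, r_point = c(50, 60),
                                r1 = 1, lb = 0, ub = 255), c(50, 60))
  expect_equal(coot_random_move(0, b = 0.5, r_point = 100, r1 = 1,
                                lb = 0, ub = 255), 50)
  # a step beyond the box is clamped to the nearest bound
  expect_equal(coot_random_move(0, b = 1, r_point = 10, r1 = 40,
                                lb = 0, ub = 255), 255)
})

test_that("chain movement is the entrywise mean", {
  expect_equal(coot_chain_move(c(2, 4), c(6, 8)), c(4, 6))
  x <- c(1.5, -2, 7)
  expect_equal(coot_chain_move(x, x), x)
  expect_equal(coot_chain_move(0, 255), 127.5)
  expect_error(coot_chain_move(c(1, 2), 3), "equal length")
})

test_that("leader labels cycle 1..NL over the follower counter", {
  expect_equal(coot_leader_index(5, 3), 3L)
  expect_equal(coot_leader_index(3, 3), 1L)
  expect_equal(coot_leader_index(0, 4), 1L)
  expect_error(coot_leader_index(1, 0), "n_leaders")
})

test_that("follower movement around the leader matches fixed-draw values", {
  expect_equal(coot_follow_move(4, 10, r2 = 0.5, r3 = 0, lb = -100, ub = 100),
               16)   # 2L - C
  expect_equal(coot_follow_move(4, 10, r2 = 0, r3 = 0.7, lb = -100, ub = 100),
               10)   # r2 = 0 lands on the leader
  expect_equal(coot_follow_move(4, 10, r2 = 0.9, r3 = 0.25,
                                lb = -100, ub = 100), 10)  # cos(pi/2) = 0
})

test_that("leader movement around gbest matches fixed-draw values", {
  expect_equal(coot_leader_move(4, 10, b = 1, r3 = 0, r4 = 1, r5 = 0.3,
                                lb = -100, ub = 100), 16)
  expect_equal(coot_leader_move(4, 10, b = 1, r3 = 0, r4 = 1, r5 = 0.7,
                                lb = -100, ub = 100), -4)
  expect_equal(coot_leader_move(4, 10, b = 1, r3 = 0, r4 = 1, r5 = 0.7,
                                lb = 0, ub = 100), 0)   # clamped
  expect_equal(coot_leader_move(4, 10, b = 1, r3 = 0.1, r4 = 0, r5 = 0.2,
                                lb = -100, ub = 100), 10)
})

test_that("Mantegna sigma matches the high-precision gamma oracle", {
  expect_equal(levy_sigma(1.0), 1.0, tolerance = 1e-12)
  # frozen from a 30-digit evaluation of the gamma expression
  expect_equal(levy_sigma(1.5), 0.696574502557697, tolerance = 1e-12)
  expect_error(levy_sigma(0), "beta")
  expect_error(levy_sigma(2.5), "beta")
})

test_that("Levy steps have the documented fixed-draw values", {
  d <- 3L
  expect_equal(levy_step(d, 1.5, u = rep(0, d), v = rep(1, d)), rep(0, d))
  expect_equal(levy_step(d, 1.5, u = rep(1, d), v = rep(1, d)),
               rep(0.01 * levy_sigma(1.5), d), tolerance = 1e-12)
})

test_that("Levy steps are heavy-tailed", {
  set.seed(42)
  steps <- levy_step(10000L, 1.5)
  expect_gt(excess_kurtosis(steps), 10)
  expect_gt(max(abs(steps)), 50 * stats::median(abs(steps)))
})

test_that("Levy perturbation applies and clamps the step", {
  expect_equal(levy_perturb(c(1, 2), alpha = 1, lb = 0, ub = 10,
                            step = c(0, 0)), c(1, 2))
  expect_equal(levy_perturb(c(1, 2), alpha = 0, lb = 0, ub = 10,
                            step = c(5, 5)), c(1, 2))
  expect_equal(levy_perturb(c(0, 0), alpha = 1, lb = -1, ub = 1,
                            step = c(0.5, -0.5)), c(0.5, -0.5))
  # multiplicative mode is the literal entrywise product
  expect_equal(levy_perturb(c(2, 4), alpha = 0.5, lb = 0, ub = 10,
                            step = c(1, 1), mode = "multiplicative"),
               c(1, 2))
})

test_that("opposition is an involution with the documented fixed points", {
  expect_equal(opposite_point(200, 0, 255), 55)
  expect_equal(opposite_point(2, 2, 10), 10)
  mid <- (0 + 255) / 2
  expect_equal(opposite_point(mid, 0, 255), mid)
  set.seed(7)
  for (i in 1:25) {
    lb <- stats::runif(4, -10, 0); ub <- lb + stats::runif(4, 1, 20)
    x <- lb + stats::runif(4) * (ub - lb)
    expect_equal(opposite_point(opposite_point(x, lb, ub), lb, ub), x,
                 tolerance = 1e-12)
  }
})

test_that("quasi-opposite points stay between the centre and the opposite", {
  expect_equal(quasi_opposite_point(0.2, 0, 1, u = 0), 0.5)
  expect_equal(quasi_opposite_point(0.2, 0, 1, u = 1), 0.8)
  centre <- 0.5
  expect_equal(quasi_opposite_point(centre, 0, 1, u = 0.37), centre)
  set.seed(11)
  x <- stats::runif(5000, 0, 1)
  q <- quasi_opposite_point(x, 0, 1)
  opp <- opposite_point(x, 0, 1)
  expect_true(all(q >= pmin(centre, opp) - 1e-12))
  expect_true(all(q <= pmax(centre, opp) + 1e-12))
})
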