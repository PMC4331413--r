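test_that("dense solver reproduces closed-form balances", {
  a <- 0.3; b <- 0.7
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE)
  expect_equal(solve_dense(Q)$pi, c(b, a) / (a + b), tolerance = 1e-14)
  # two independent gates: product form over the 4x4 descriptor
  Q4 <- kron_sum(Q, Q)
  expect_equal(solve_dense(Q4)$pi,
               as.numeric(kronecker(c(b, a) / (a + b), c(b, a) / (a + b))),
               tolerance = 1e-12)
  # symmetric birth-death hemichannel: Binomial(6, 1/2)
  expect_equal(solve_dense(oracle_birth_death(0.004, 0.004))$pi,
               dbinom(0:6, 6, 0.5), tolerance = 1e-12)
  # asymmetric: Binomial(6, a/(a+b)) over the closed count
  expect_equal(solve_dense(oracle_birth_death(0.006, 0.002))$pi,
               dbinom(0:6, 6, 0.75), tolerance = 1e-12)
})

test_that("dense solver flags reducible chains", {
  Q <- matrix(0, 2, 2)  # absorbing everywhere: rank deficient beyond 1
  expect_error(solve_dense(Q), "reducible")
})

test_that("banded solver agrees with the dense solver on all three models", {
  p2 <- default_two_state_params()
  p3 <- default_three_state_params()
  g2 <- build_generator("two_state_12", p2, vj = 40)
  expect_equal(solve_banded(g2, 7, 7)$pi, solve_dense(g2)$pi, tolerance = 1e-10)
  g6 <- build_generator("three_state_6", p3, vj = 40)
  expect_equal(solve_banded(g6)$pi, solve_dense(g6)$pi, tolerance = 1e-10)
  # tridiagonal two-state chain with the minimal band
  a <- 0.3; b <- 0.7
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE)
  expect_equal(solve_banded(Q, 1, 1)$pi, c(b, a) / (a + b), tolerance = 1e-12)
})

test_that("a band too narrow to hold the nonzeros is rejected", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  expect_error(solve_banded(gen, 3, 3), "Invalid band")
})

test_that("block recursive solution matches dense to the direct-method accuracy", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  pi_rec <- solve_block_recursive(gen)$pi
  pi_dense <- solve_dense(gen)$pi
  expect_lt(max(abs(pi_rec - pi_dense)), 1e-12)
  # constant-rate regime: product of binomials closed form
  p0 <- gating_params(A = 0, Ro = Inf, Rc = Inf)
  gen0 <- build_generator("two_state_12", p0, vj = 40)
  bn <- dbinom(0:6, 6, 0.5)
  expect_equal(solve_block_recursive(gen0)$pi, as.numeric(kronecker(bn, bn)),
               tolerance = 1e-12)
})

test_that("block recursive handles the smallest (two-block) case and rejects varying blocks", {
  # 2-block toy generator with diagonal off-blocks
  set.seed(31)
  D1 <- diag(runif(3, 0.001, 0.01))
  D2 <- diag(runif(3, 0.001, 0.01))
  A1 <- matrix(runif(9, 0, 0.005), 3); diag(A1) <- 0
  A2 <- matrix(runif(9, 0, 0.005), 3); diag(A2) <- 0
  Q <- rbind(cbind(A1, D1), cbind(D2, A2))
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  toy <- list(Q = Q, block_sizes = c(3L, 3L))
  expect_equal(solve_block_recursive(toy)$pi, solve_dense(Q)$pi,
               tolerance = 1e-12)
  g6 <- build_generator("three_state_6", default_three_state_params(), vj = 40)
  expect_error(solve_block_recursive(g6), "equal block sizes")
})

test_that("block Gauss-Seidel converges to the dense solution on all three models", {
  p2 <- default_two_state_params()
  p3 <- default_three_state_params()
  for (case in list(list("two_state_12", p2), list("three_state_6", p3),
                    list("three_state_12", p3))) {
    gen <- build_generator(case[[1]], case[[2]], vj = 40)
    res <- solve_block_gauss_seidel(gen, solver_options(epsilon = 1e-10))
    expect_true(res$converged)
    expect_gt(res$outer_iterations, 1)
    expect_lt(max(abs(res$pi - solve_dense(gen)$pi)), 1e-8)
  }
})

test_that("block Gauss-Seidel declares convergence after one sweep from the fixed point", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  exact <- solve_dense(gen)$pi
  res <- solve_block_gauss_seidel(gen, solver_options(initial_vector = exact))
  expect_equal(res$outer_iterations, 1L)
  expect_true(res$converged)
})

test_that("outer-iteration counts are nondecreasing as the tolerance tightens", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  eps <- 10^-(4:15)
  iters <- vapply(eps, function(e) {
    solve_block_gauss_seidel(gen, solver_options(epsilon = e))$outer_iterations
  }, integer(1))
  expect_true(all(diff(iters) >= 0))
  expect_gt(iters[length(iters)], iters[1])
})

test_that("block Gauss-Seidel residuals decrease monotonically over sweeps", {
  p3 <- default_three_state_params()
  for (kind in c("two_state_12", "three_state_6", "three_state_12")) {
    gen <- build_generator(kind, p3, vj = 40)
    res <- solve_block_gauss_seidel(gen, solver_options(epsilon = 1e-10))
    # sweeps from the uniform start can overshoot briefly; monotone after the
    # initial transient, and decreasing overall
    h <- res$residual_history
    expect_true(all(diff(h[-(1:3)]) <= 1e-14))
    expect_lt(h[length(h)], h[1])
  }
})

test_that("the convergence check is an entrywise max-difference test", {
  expect_true(convergence_check(c(0.5, 0.5), c(0.5, 0.5), 1e-12))
  expect_false(convergence_check(c(0, 2e-6), c(0, 0), 1e-6))
  expect_true(convergence_check(c(9e-7, -9e-7), c(0, 0), 1e-6))
  expect_error(convergence_check(1:3 / 6, 1:2 / 3, 1e-6), "equal length")
})

test_that("steady states are invariant to global rescaling of the generator", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  pi1 <- solve_dense(gen$Q)$pi
  expect_equal(solve_dense(7.3 * gen$Q)$pi, pi1, tolerance = 1e-12)
  sc <- list(Q = 7.3 * gen$Q, block_sizes = gen$block_sizes)
  expect_equal(solve_block_recursive(sc)$pi, pi1, tolerance = 1e-12)
})

test_that("DTMC and CTMC formulations share the steady state", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  Q <- gen$Q
  n <- nrow(Q)
  tau <- 0.9 / max(abs(diag(Q)))      # I + tau*Q is stochastic
  P <- diag(n) + tau * Q
  expect_true(all(P >= 0))
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i1]); v <- v / sum(v)
  expect_equal(v, solve_dense(Q)$pi, tolerance = 1e-10)
})

test_that("the group inverse satisfies its defining identities", {
  a <- 0.3; b <- 0.7
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE)
  Qh <- group_inverse(Q)
  expect_equal(Q %*% Qh %*% Q, Q, tolerance = 1e-9)
  expect_equal(Qh %*% Q %*% Qh, Qh, tolerance = 1e-9)
  expect_equal(Q %*% Qh, Qh %*% Q, tolerance = 1e-9)
  # rank-one closed form for the two-state chain: Q# = Q / (a+b)^2
  expect_equal(Qh, Q / (a + b)^2, tolerance = 1e-12)
  # reducible chain refused
  expect_error(group_inverse(matrix(0, 2, 2)), "irreducible")
})

test_that("the steady-state perturbation bound holds for random small perturbations", {
  set.seed(33)
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 40)
  Q <- gen$Q
  Qh <- group_inverse(Q)
  pi0 <- solve_dense(Q)$pi
  nQh <- norm(Qh, "I")
  for (i in 1:100) {
    Qp <- Q
    off <- which(Q > 0)
    Qp[off] <- Q[off] * (1 + runif(length(off), -1e-3, 1e-3))
    diag(Qp) <- 0; diag(Qp) <- -rowSums(Qp)
    dpi <- solve_dense(Qp)$pi - pi0
    expect_lte(sum(abs(dpi)) / sum(abs(pi0)), nQh * norm(Qp - Q, "I"))
  }
})

test_that("the solver front end dispatches all four methods consistently", {
  gen <- build_generator("two_state_12", default_two_state_params(), vj = 20)
  ref <- solve_steady_state(gen, "dense_ge")$pi
  for (m in c("banded_ge", "block_recursive")) {
    expect_equal(solve_steady_state(gen, m)$pi, ref, tolerance = 1e-10)
  }
  bgs <- solve_steady_state(gen, "block_gauss_seidel",
                            solver_options(epsilon = 1e-12))
  expect_equal(bgs$pi, ref, tolerance = 1e-9)
})
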