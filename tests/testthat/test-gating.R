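test_that("Boltzmann transition probabilities behave at the anchor points", {
  p <- gating_params(A = 0.04, P = 1, K = 0.01, V0 = 25)
  # at V = V0 the two probabilities are equal at K/2
  at_v0 <- transition_probabilities(p, 25)
  expect_equal(at_v0$p_oc, 0.005)
  expect_equal(at_v0$p_co, 0.005)
  # direct evaluation at V = 40: k = exp(0.6)
  at40 <- transition_probabilities(p, 40)
  k <- exp(0.04 * 1 * (40 - 25))
  expect_equal(at40$p_oc, 0.01 * k / (1 + k), tolerance = 1e-15)
  expect_equal(at40$p_co, 0.01 / (1 + k), tolerance = 1e-15)
  # saturation limits
  sat <- transition_probabilities(p, 1e6)
  expect_equal(sat$p_oc, 0.01)
  expect_equal(sat$p_co, 0)
  # equilibrium ratio equals k exactly (K cancels)
  expect_equal(at40$p_oc / at40$p_co, k, tolerance = 1e-12)
})

test_that("p_oc is nondecreasing and p_co nonincreasing in P*(V - V0)", {
  p <- gating_params(A = 0.05, P = 1, K = 0.01, V0 = 20)
  v <- seq(-100, 100, by = 1)
  pr <- transition_probabilities(p, v)
  expect_true(all(diff(pr$p_oc) >= 0))
  expect_true(all(diff(pr$p_co) <= 0))
  pneg <- gating_params(A = 0.05, P = -1, K = 0.01, V0 = 20)
  prn <- transition_probabilities(pneg, v)
  expect_true(all(diff(prn$p_oc) <= 0))
})

test_that("probability-to-rate conversion divides by tau and validates input", {
  expect_equal(rates_from_probabilities(0, 1), 0)
  expect_equal(rates_from_probabilities(0.005, 1), 0.005)
  expect_equal(rates_from_probabilities(0.004, 0.5), 0.008)
  expect_error(rates_from_probabilities(0.1, 0), "tau")
  expect_error(rates_from_probabilities(-0.1, 1), "nonnegative")
})

test_that("steady state is invariant to K and tau (kinetics-only constants)", {
  base <- solve_dense(build_generator("two_state_12", gating_params(), vj = 40))$pi
  half_K <- solve_dense(build_generator("two_state_12", gating_params(K = 0.005),
                                        vj = 40))$pi
  half_tau <- solve_dense(build_generator("two_state_12", gating_params(tau = 0.5),
                                          vj = 40))$pi
  expect_equal(half_K, base, tolerance = 1e-10)
  expect_equal(half_tau, base, tolerance = 1e-10)
})

test_that("subgate conductances carry the printed prefactors and rectify", {
  p <- gating_params(Ro = 100, Rc = 100)
  at0 <- subgate_conductances(p, 0)
  expect_equal(at0$g_o, 2)
  expect_equal(at0$g_c, 0.25)
  expect_gt(at0$g_o, at0$g_c)
  norect <- gating_params(Ro = Inf, Rc = Inf)
  for (v in c(-80, 0, 80)) {
    g <- subgate_conductances(norect, v)
    expect_equal(g$g_o, 2)
    expect_equal(g$g_c, 0.25)
  }
  expect_equal(subgate_conductances(gating_params(Ro = 100), 50)$g_o,
               2 * exp(0.5), tolerance = 1e-15)
})

test_that("hemichannel conductance sums six parallel subgates", {
  norect <- gating_params(Ro = Inf, Rc = Inf)
  expect_equal(hemichannel_conductance(0, norect, 30), 12)     # all open
  expect_equal(hemichannel_conductance(6, norect, 30), 1.5)    # all closed
  expect_equal(hemichannel_conductance(2, norect, 0), 8.5)
  expect_error(hemichannel_conductance(7, norect, 0), "0..6")
  # three-state with deep-conducts-like-closed policy
  p3 <- default_three_state_params()
  p3$Ro <- Inf; p3$Rc <- Inf
  expect_equal(hemichannel_conductance(c(2, 1), p3, 0), 2 * 2 + 1 * 0.25 + 3 * 0.25)
  expect_error(hemichannel_conductance(c(4, 4), p3, 0), "n_o")
  # constant-residual deep policy
  p3c <- gating_params(Ro = Inf, Rc = Inf, g_deep_policy = 0.1,
                       deep = list(A = 0.02, P = 1, K = 0.01, V0 = 40))
  expect_equal(hemichannel_conductance(c(0, 0), p3c, 0), 6 * 0.1)
})

test_that("voltage division splits zero voltage as zero and symmetric cases evenly", {
  p <- gating_params(Ro = Inf, Rc = Inf)
  z <- solve_voltage_division(0, 3, 3, p, p)
  expect_equal(z$v_left, 0)
  expect_equal(z$v_right, 0)
  expect_gte(z$iterations, 1)
  # mirror-symmetric states, no rectification: equal series conductances
  s <- solve_voltage_division(60, 2, 2, p, p)
  expect_equal(s$v_left, 30, tolerance = 1e-6)
  expect_equal(s$v_left + s$v_right, 60, tolerance = 1e-9)
  expect_true(s$converged)
})

test_that("voltage division matches a bisection root-finder in rectifying cases", {
  p <- gating_params(Ro = 80, Rc = 40)
  for (vj in c(20, 60, 100)) {
    for (st in list(c(1, 4), c(5, 0))) {
      res <- solve_voltage_division(vj, st[1], st[2], p, p)
      gl_fn <- function(v) hemichannel_conductance(st[1], p, v)
      gr_fn <- function(v) hemichannel_conductance(st[2], p, -v)
      v_star <- bisection_voltage_split(vj, gl_fn, gr_fn)
      expect_equal(res$v_left, v_star, tolerance = 1e-3)
      # current conservation at the returned point, 0.1% relative
      lhs <- res$v_left * res$g_left
      rhs <- res$v_right * res$g_right
      expect_lt(abs(lhs - rhs) / max(abs(lhs), abs(rhs)), 1e-3)
    }
  }
})

test_that("junctional conductance is the probability-weighted series conductance", {
  # concentrated on the all-open state without rectification: 12*12/24 = 6
  splits <- data.frame(g_left = c(12, 4), g_right = c(12, 4))
  expect_equal(junction_conductance(c(1, 0), splits), 6)
  # probability-weighted mean of series conductances 6 and 3
  splits2 <- data.frame(g_left = c(12, 6), g_right = c(12, 6))
  expect_equal(junction_conductance(c(0.5, 0.5), splits2), 4.5)
  expect_error(junction_conductance(c(0.7, 0.7), splits), "sum to 1")
  # degenerate zero-conductance states contribute zero
  splits3 <- data.frame(g_left = c(0, 12), g_right = c(0, 12))
  expect_equal(junction_conductance(c(0.5, 0.5), splits3), 3)
})

test_that("junctional conductance equals a brute-force sum over all 49 states", {
  p <- default_two_state_params()
  gen <- build_generator("two_state_12", p, vj = 0)
  pi <- solve_dense(gen)$pi
  gj <- junction_conductance(pi, gen)
  manual <- 0
  for (i in seq_len(49)) {
    st <- gen$state_space$states[i, ]
    sp <- solve_voltage_division(0, st$n_l, st$n_r, p, p)
    manual <- manual + pi[i] * sp$g_left * sp$g_right / (sp$g_left + sp$g_right)
  }
  expect_equal(gj, manual, tolerance = 1e-12)
})

test_that("gating parameters round-trip through the YAML config reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("A: 0.05", "P: -1", "K: 0.008", "V0: 30", "Ro: 120", "Rc: 60",
               "tau: 2", "deep.A: 0.02", "deep.P: 1", "deep.K: 0.004",
               "deep.V0: 45", "g_deep_policy: closed"), path)
  p <- read_gating_params(path)
  expect_s3_class(p, "gating_params")
  expect_equal(p$A, 0.05)
  expect_equal(p$P, -1)
  expect_equal(p$tau, 2)
  expect_equal(p$deep$V0, 45)
  # nested form is accepted too
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("A: 0.05", "P: 1", "K: 0.008", "V0: 30",
               "deep:", "  A: 0.02", "  P: 1", "  K: 0.004", "  V0: 45"), path2)
  expect_equal(read_gating_params(path2)$deep$K, 0.004)
})

test_that("invalid gating parameters are rejected", {
  expect_error(gating_params(P = 0), "P")
  expect_error(gating_params(K = -1))
  expect_error(gating_params(tau = 0))
  expect_error(gating_params(Ro = 0), "Ro")
  expect_error(gating_params(deep = list(A = 0.1, P = 1)), "deep")
})
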