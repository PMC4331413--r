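# Shared fixtures: parameter sets and small reference generators built in code.

default_two_state_params <- function() gating_params()

default_three_state_params <- function() {
  gating_params(deep = list(A = 0.02, P = 1, K = 0.01, V0 = 40))
}

# Independent brute-force composition oracle: enumerates every global state of
# k independent automata with constant rates and fills the generator directly
# from the transition lists, without Kronecker algebra.
brute_force_generator <- function(automata, rate_table) {
  ns <- vapply(automata, function(a) a$n_states, integer(1))
  k <- length(ns)
  grids <- rev(lapply(ns, seq_len))
  states <- as.matrix(rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  N <- nrow(states)
  idx_of <- function(s) {
    i <- 0
    for (a in seq_len(k)) i <- i * ns[a] + (s[a] - 1)
    i + 1
  }
  Q <- matrix(0, N, N)
  for (r in seq_len(N)) {
    s <- states[r, ]
    for (a in seq_len(k)) {
      tr <- automata[[a]]$transitions
      for (t in seq_len(nrow(tr))) {
        if (tr$from[t] != s[a]) next
        s2 <- s
        s2[a] <- tr$to[t]
        Q[r, idx_of(s2)] <- Q[r, idx_of(s2)] + tr$mult[t] * rate_table[[tr$label[t]]]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Closed-form 7-state hemichannel generator over the closed-subgate count,
# written out directly from the birth-death rules (test-side oracle).
oracle_birth_death <- function(a, b) {
  Q <- matrix(0, 7, 7)
  for (n in 0:5) Q[n + 1, n + 2] <- (6 - n) * a
  for (n in 1:6) Q[n + 1, n] <- n * b
  diag(Q) <- -rowSums(Q)
  Q
}

# Bisection oracle for the series voltage split: root of the current-balance
# residual f(v_l) = v_l * g_l(v_l) - (Vj - v_l) * g_r(Vj - v_l).
bisection_voltage_split <- function(Vj, gl_fn, gr_fn, tol = 1e-10) {
  f <- function(v) v * gl_fn(v) - (Vj - v) * gr_fn(Vj - v)
  lo <- min(0, Vj); hi <- max(0, Vj)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
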