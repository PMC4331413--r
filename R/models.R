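#' Enumerate the global state space of a channel model
#'
#' Three model variants are supported:
#' * `"two_state_12"` — both hemichannels gate, each subgate is open/closed;
#'   global states are pairs `(n_l, n_r)` of closed-subgate counts, 49 states
#'   in 7 blocks of 7 (left hemichannel is the slow index).
#' * `"three_state_6"` — only the left hemichannel gates, each subgate is
#'   open/closed/deep-closed; states are tuples `(n_o, n_c)` with
#'   `n_o + n_c <= 6`, 28 states in blocks of sizes 7, 6, ..., 1 grouped by
#'   `n_o` ascending (`n_c` ascending within a block).
#' * `"three_state_12"` — both hemichannels have three-state subgates; states
#'   are pairs of such tuples, `28^2 = 784` states in 28 blocks of 28.
#'
#' @param kind Model selector string (see above).
#' @return An object of class `gj_state_space`: list with `kind`, `states`
#'   (tibble, one row per global state in generator order), `block_sizes`,
#'   and `n` (total state count).
#' @examples
#' enumerate_states("two_state_12")$n     # 49
#' enumerate_states("three_state_6")$n    # 28
#' @export
enumerate_states <- function(kind) {
  kind <- match.arg(kind, c("two_state_12", "three_state_6", "three_state_12"))
  hc3 <- function() {
    # blocks by n_o ascending, n_c ascending within block
    n_o <- unlist(lapply(0:6, function(o) rep(o, 7 - o)))
    n_c <- unlist(lapply(0:6, function(o) 0:(6 - o)))
    tibble::tibble(n_o = n_o, n_c = n_c)
  }
  out <- switch(kind,
    two_state_12 = {
      g <- expand.grid(n_r = 0:6, n_l = 0:6)   # n_l slow
      list(states = tibble::tibble(n_l = g$n_l, n_r = g$n_r),
           block_sizes = rep(7L, 7))
    },
    three_state_6 = {
      list(states = hc3(), block_sizes = 7:1)
    },
    three_state_12 = {
      h <- hc3()
      idx <- expand.grid(r = seq_len(28), l = seq_len(28))  # left slow
      list(states = tibble::tibble(
             n_o_l = h$n_o[idx$l], n_c_l = h$n_c[idx$l],
             n_o_r = h$n_o[idx$r], n_c_r = h$n_c[idx$r]),
           block_sizes = rep(28L, 28))
    })
  structure(list(kind = kind, states = out$states,
                 block_sizes = as.integer(out$block_sizes),
                 n = nrow(out$states)),
            class = "gj_state_space")
}

#' @export
print.gj_state_space <- function(x, ...) {
  cat(sprintf("Gap-junction state space '%s': %d states, %d blocks (%s)\n",
              x$kind, x$n, length(x$block_sizes),
              paste(x$block_sizes, collapse = ", ")))
  invisible(x)
}

#' Transitions available to one hemichannel from a gating state
#'
#' Two-state hemichannels: from `n` closed subgates, open one (`co`, rate
#' multiplicity `n`) or close one (`oc`, multiplicity `6 - n`). Three-state
#' hemichannels from `(n_o, n_c)`: a closed subgate opens (`co`, multiplicity
#' `n_c`), an open one closes (`oc`, multiplicity `n_o`), a deep-closed one
#' recovers to closed (`dc`, multiplicity `6 - n_o - n_c`), or a closed one
#' sinks deeper (`cd`, multiplicity `n_c`). Moves that would leave the state
#' simplex are not listed.
#'
#' @param state Integer `n_closed` (two-state) or `c(n_o, n_c)` (three-state).
#' @param kind `"two_state"` or `"three_state"`.
#' @return Tibble with columns `target` (list of target states), `label`,
#'   `mult`, containing only moves with positive multiplicity.
#' @export
hemichannel_transitions <- function(state, kind = c("two_state", "three_state")) {
  kind <- match.arg(kind)
  if (kind == "two_state") {
    n <- state[1]
    stopifnot(n >= 0, n <= 6)
    out <- tibble::tibble(
      target = list(n - 1, n + 1),
      label = c("co", "oc"),
      mult = c(n, 6 - n))
  } else {
    n_o <- state[1]; n_c <- state[2]
    stopifnot(n_o >= 0, n_c >= 0, n_o + n_c <= 6)
    out <- tibble::tibble(
      target = list(c(n_o + 1, n_c - 1), c(n_o - 1, n_c + 1),
                    c(n_o, n_c + 1), c(n_o, n_c - 1)),
      label = c("co", "oc", "dc", "cd"),
      mult = c(n_c, n_o, 6 - n_o - n_c, n_c))
  }
  out[out$mult > 0, ]
}

# Internal: the hemichannel as a local automaton (states in generator order).
hemichannel_automaton <- function(kind = c("two_state", "three_state")) {
  kind <- match.arg(kind)
  if (kind == "two_state") {
    states <- data.frame(n = 0:6)
    idx <- function(s) as.integer(s[1] + 1)
  } else {
    ss <- enumerate_states("three_state_6")$states
    states <- as.data.frame(ss)
    key <- paste(ss$n_o, ss$n_c)
    idx <- function(s) match(paste(s[1], s[2]), key)
  }
  rows <- lapply(seq_len(nrow(states)), function(i) {
    s <- as.numeric(states[i, ])
    tr <- hemichannel_transitions(s, kind)
    if (!nrow(tr)) return(NULL)
    data.frame(from = i,
               to = vapply(tr$target, idx, integer(1)),
               label = tr$label, mult = tr$mult)
  })
  local_automaton(nrow(states), do.call(rbind, rows))
}

# Internal: per-state hemichannel conductance, vectorized over voltages.
# counts is a matrix with one row per global state: column "n" (two-state) or
# columns "n_o","n_c" (three-state).
state_conductance_fn <- function(counts, params, kind, orientation = 1) {
  force(counts); force(params); force(orientation)
  if (kind == "two_state") {
    n <- counts[, 1]
    function(v) {
      g <- subgate_conductances(params, orientation * v)
      n * g$g_c + (6 - n) * g$g_o
    }
  } else {
    n_o <- counts[, 1]; n_c <- counts[, 2]; n_d <- 6 - n_o - n_c
    function(v) {
      g <- subgate_conductances(params, orientation * v)
      n_o * g$g_o + n_c * g$g_c + n_d * deep_conductance(params, g$g_c)
    }
  }
}

#' Build the global infinitesimal generator of a channel model
#'
#' Enumerates the model's state space, solves the series voltage division for
#' every global state (cached on the result), evaluates the Boltzmann
#' transition rates of each hemichannel at its own voltage, and composes the
#' global generator by the generalized Kronecker-sum construction. The
#' resulting matrix has nonnegative off-diagonals, zero row sums, and the
#' block structure of the selected model (block tridiagonal with diagonal
#' off-blocks for `two_state_12`; varying block sizes for `three_state_6`;
#' a layered block pattern for `three_state_12`).
#'
#' @param kind Model selector, as in [enumerate_states()].
#' @param params_left,params_right [gating_params()] for the two hemichannels
#'   (three-state kinds require the `deep` parameter set).
#' @param vj Transjunctional voltage, mV.
#' @param right_orientation Sign with which the right hemichannel senses the
#'   voltage across it (default `-1`: antiparallel docking).
#' @return An object of class `gj_generator`: list with the generator matrix
#'   `Q`, `kind`, `state_space`, `block_sizes`, measured `bandwidth`
#'   (`k1`, `k2`, `m`), the per-state voltage-split cache `vsplits` (tibble),
#'   the parameter sets and `vj`.
#' @export
build_generator <- function(kind, params_left, params_right = params_left,
                            vj = 0, right_orientation = -1) {
  stopifnot(inherits(params_left, "gating_params"),
            inherits(params_right, "gating_params"),
            is.finite(vj))
  ss <- enumerate_states(kind)
  two <- ss$kind == "two_state_12"
  if (!two && (is.null(params_left$deep) ||
               (ss$kind == "three_state_12" && is.null(params_right$deep)))) {
    stop("Three-state models need the `deep` parameter set.", call. = FALSE)
  }

  st <- ss$states
  counts_l <- switch(ss$kind,
    two_state_12   = cbind(n = st$n_l),
    three_state_6  = cbind(n_o = st$n_o, n_c = st$n_c),
    three_state_12 = cbind(n_o = st$n_o_l, n_c = st$n_c_l))
  counts_r <- switch(ss$kind,
    two_state_12   = cbind(n = st$n_r),
    three_state_6  = cbind(n_o = rep(6L, ss$n), n_c = rep(0L, ss$n)),
    three_state_12 = cbind(n_o = st$n_o_r, n_c = st$n_c_r))
  kind_l <- if (two) "two_state" else "three_state"
  kind_r <- if (ss$kind == "two_state_12") "two_state" else "three_state"

  gl_fn <- state_conductance_fn(counts_l, params_left, kind_l, orientation = 1)
  gr_fn <- state_conductance_fn(counts_r, params_right, kind_r,
                                orientation = right_orientation)
  vd <- voltage_division(vj, gl_fn, gr_fn, n = ss$n)
  if (!all(vd$converged)) {
    warning(sprintf("Voltage division unconverged for %d state(s) at Vj = %g mV.",
                    sum(!vd$converged), vj), call. = FALSE)
  }
  vsplits <- tibble::tibble(
    v_left = vd$v_left, v_right = vd$v_right,
    g_left = vd$g_left, g_right = vd$g_right,
    iterations = vd$iterations, converged = vd$converged)

  # per-global-state rate tables, one set per hemichannel
  rate_set <- function(params, v_eff) {
    p <- transition_probabilities(params, v_eff)
    out <- list(oc = rates_from_probabilities(p$p_oc, params$tau),
                co = rates_from_probabilities(p$p_co, params$tau))
    if (!is.null(params$deep)) {
      pd <- transition_probabilities(deep_as_params(params), v_eff)
      out$cd <- rates_from_probabilities(pd$p_oc, params$tau)
      out$dc <- rates_from_probabilities(pd$p_co, params$tau)
    }
    out
  }
  rates_l <- rate_set(params_left, vd$v_left)
  rates_r <- if (ss$kind == "three_state_6") NULL else
    rate_set(params_right, right_orientation * vd$v_right)
  tables <- list(rates_l, rates_r)
  rate_fn <- function(label, automaton, state_rows) {
    tables[[automaton]][[label]][state_rows]
  }

  automata <- switch(ss$kind,
    two_state_12   = list(hemichannel_automaton("two_state"),
                          hemichannel_automaton("two_state")),
    three_state_6  = list(hemichannel_automaton("three_state")),
    three_state_12 = list(hemichannel_automaton("three_state"),
                          hemichannel_automaton("three_state")))

  Q <- assemble_functional_generator(automata, rate_fn)
  structure(list(Q = Q, kind = ss$kind, state_space = ss,
                 block_sizes = ss$block_sizes,
                 bandwidth = matrix_bandwidth(Q),
                 vsplits = vsplits,
                 params_left = params_left, params_right = params_right,
                 vj = vj, right_orientation = right_orientation),
            class = "gj_generator")
}

#' @export
print.gj_generator <- function(x, ...) {
  cat(sprintf("Gap-junction CTMC generator '%s' at Vj = %g mV\n", x$kind, x$vj))
  cat(sprintf("  %d states, %d blocks, bandwidth m = %d (k1 = %d, k2 = %d)\n",
              x$state_space$n, length(x$block_sizes),
              x$bandwidth$m, x$bandwidth$k1, x$bandwidth$k2))
  invisible(x)
}

#' Compare the lumped 49-state model against the full 4096-state subgate model
#'
#' In the constant-rate regime (state-independent rates, i.e. `A = 0`, where
#' exact lumpability holds) the 12 two-state subgates are independent
#' automata. This builds the full `2^12 = 4096`-state generator by a 12-fold
#' Kronecker sum, solves its steady state (sparse LU on the grounded system),
#' aggregates it by the closed-subgate counts `(n_l, n_r)`, and compares with
#' the steady state of the lumped 49-state birth-death-product model. Both
#' marginals equal `Binomial(6, lambda_oc / (lambda_oc + lambda_co))` over the
#' closed count.
#'
#' @param params Optional [gating_params()] with `A = 0` (the constant-rate
#'   regime); a nonzero `A` makes rates state-dependent, where lumpability is
#'   not guaranteed, and raises an error.
#' @param vj Transjunctional voltage (enters only through the voltage split,
#'   which cannot change constant rates; kept for interface symmetry).
#' @param rates Optional explicit constant rates, named numeric
#'   `c(oc = ..., co = ...)`; overrides `params`-derived rates and allows
#'   asymmetric opening/closing speeds.
#' @return List of class `gj_lumping` with `aggregated` and `lumped` 7x7
#'   steady-state matrices (rows `n_l`, columns `n_r`), the closed-state
#'   probability `p_closed`, `max_abs_diff`, and `n_unlumped = 4096`.
#' @export
lump_full_subgate_model <- function(params = NULL, vj = 0, rates = NULL) {
  if (is.null(rates)) {
    stopifnot(inherits(params, "gating_params"))
    if (params$A != 0) {
      stop(paste("Unsupported regime: rates are state-dependent (A != 0);",
                 "exact lumpability is only guaranteed for constant rates."),
           call. = FALSE)
    }
    p <- transition_probabilities(params, 0)
    rates <- c(oc = rates_from_probabilities(p$p_oc, params$tau),
               co = rates_from_probabilities(p$p_co, params$tau))
  }
  a <- unname(rates[["oc"]]); b <- unname(rates[["co"]])
  stopifnot(a > 0, b > 0)

  # full model: 12 independent two-state automata (state 1 open, 2 closed)
  q1 <- Matrix::Matrix(matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE), sparse = TRUE)
  ks <- function(A, B) {
    kronecker(A, Matrix::Diagonal(nrow(B))) + kronecker(Matrix::Diagonal(nrow(A)), B)
  }
  Q <- Reduce(ks, rep(list(q1), 12))
  n <- nrow(Q)                                   # 4096
  Qt <- Matrix::t(Q)
  y <- Matrix::solve(Qt[-n, -n], -Qt[-n, n])
  pi_full <- c(as.numeric(y), 1)
  pi_full <- pi_full / sum(pi_full)

  # closed counts per automaton (first automaton slow)
  s <- 0:(n - 1)
  bits <- vapply(1:12, function(i) (s %/% 2^(12 - i)) %% 2, numeric(n))
  n_l <- rowSums(bits[, 1:6]); n_r <- rowSums(bits[, 7:12])
  aggregated <- matrix(0, 7, 7, dimnames = list(n_l = 0:6, n_r = 0:6))
  for (i in seq_len(n)) {
    aggregated[n_l[i] + 1, n_r[i] + 1] <- aggregated[n_l[i] + 1, n_r[i] + 1] + pi_full[i]
  }

  # lumped model: Kronecker sum of two 7-state birth-death hemichannels
  bd <- birth_death_generator(a, b)
  pi_lumped <- solve_dense(kron_sum(bd, bd))$pi
  lumped <- matrix(pi_lumped, 7, 7, byrow = TRUE, dimnames = list(n_l = 0:6, n_r = 0:6))

  structure(list(aggregated = aggregated, lumped = lumped,
                 p_closed = a / (a + b),
                 max_abs_diff = max(abs(aggregated - lumped)),
                 n_unlumped = as.integer(n)),
            class = "gj_lumping")
}

# Internal: 7-state hemichannel birth-death generator over the closed count,
# with constant closing rate a (o -> c) and opening rate b (c -> o).
birth_death_generator <- function(a, b) {
  Q <- matrix(0, 7, 7)
  for (n in 0:5) Q[n + 1, n + 2] <- (6 - n) * a
  for (n in 1:6) Q[n + 1, n] <- n * b
  diag(Q) <- -rowSums(Q)
  Q
}

#' Export a generator as plain-text sparse triplets
#'
#' Writes the nonzero entries as tab-separated `(row, col, value)` with 1-based
#' indices, for external inspection of the sparsity structure.
#'
#' @param generator A [build_generator()] result or a plain matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_generator_triplets <- function(generator, path) {
  Q <- if (inherits(generator, "gj_generator")) generator$Q else as.matrix(generator)
  nz <- which(Q != 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, "row"], col = nz[, "col"], value = Q[nz])
  df <- df[order(df$row, df$col), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
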