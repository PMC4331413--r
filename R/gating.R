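#' Subgate gating parameters
#'
#' Bundles the per-subgate biophysical constants of the Boltzmann gating model:
#' voltage sensitivity `A` (1/mV), gating polarity `P` (+1 or -1), kinetic
#' constant `K` (dimensionless; scales both opening and closing kinetics but
#' cancels in the equilibrium ratio, so the steady state is K-invariant),
#' half-activation voltage `V0` (mV, where open and closed transition
#' probabilities are equal), rectification constants `Ro`, `Rc` (mV; `Inf`
#' means no rectification), and the probability-to-rate time step `tau`.
#' Three-state subgates add an independent parameter set `deep` of the same
#' Boltzmann form governing the closed <-> deep-closed transition, plus a
#' policy for the deep state's conductance.
#'
#' @param A Gating sensitivity, 1/mV; `A > 0` (use `A = 0` only for the
#'   degenerate constant-rate regime used in lumping checks).
#' @param P Gating polarity, `+1` or `-1`.
#' @param K Kinetic constant, `> 0`.
#' @param V0 Half-activation voltage, mV.
#' @param Ro,Rc Open/closed-state rectification constants, mV; finite nonzero
#'   or `Inf` for "no rectification".
#' @param tau Time step converting transition probabilities to rates, `> 0`.
#' @param deep Optional named list with elements `A`, `P`, `K`, `V0` for the
#'   closed <-> deep-closed Boltzmann gate (three-state models).
#' @param g_deep_policy Deep-state conductance rule: `"closed"` (deep conducts
#'   like closed, the default) or a single nonnegative number used as a
#'   constant residual conductance.
#' @return An object of class `gating_params`.
#' @examples
#' gating_params(A = 0.04, P = 1, K = 0.01, V0 = 25)
#' @export
gating_params <- function(A = 0.04, P = 1, K = 0.01, V0 = 25,
                          Ro = 100, Rc = 100, tau = 1,
                          deep = NULL, g_deep_policy = "closed") {
  stopifnot(is.numeric(A), length(A) == 1L, A >= 0, is.finite(A))
  if (!P %in% c(-1, 1)) stop("`P` must be +1 or -1.", call. = FALSE)
  stopifnot(K > 0, is.finite(K), is.finite(V0), tau > 0, is.finite(tau))
  if (Ro == 0 || Rc == 0 || is.na(Ro) || is.na(Rc)) {
    stop("`Ro` and `Rc` must be nonzero (Inf = no rectification).", call. = FALSE)
  }
  if (!is.null(deep)) {
    req <- c("A", "P", "K", "V0")
    if (!all(req %in% names(deep))) {
      stop("`deep` needs elements A, P, K, V0.", call. = FALSE)
    }
    if (!deep$P %in% c(-1, 1)) stop("`deep$P` must be +1 or -1.", call. = FALSE)
    stopifnot(deep$A >= 0, deep$K > 0, is.finite(deep$V0))
  }
  if (is.character(g_deep_policy)) {
    g_deep_policy <- match.arg(g_deep_policy, "closed")
  } else {
    stopifnot(is.numeric(g_deep_policy), length(g_deep_policy) == 1L,
              g_deep_policy >= 0, is.finite(g_deep_policy))
  }
  structure(list(A = A, P = P, K = K, V0 = V0, Ro = Ro, Rc = Rc, tau = tau,
                 deep = deep, g_deep_policy = g_deep_policy),
            class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat("Subgate gating parameters\n")
  cat(sprintf("  A = %g /mV, P = %+d, K = %g, V0 = %g mV\n", x$A, x$P, x$K, x$V0))
  cat(sprintf("  Ro = %g mV, Rc = %g mV, tau = %g\n", x$Ro, x$Rc, x$tau))
  if (!is.null(x$deep)) {
    cat(sprintf("  deep gate: A = %g /mV, P = %+d, K = %g, V0 = %g mV (g_deep: %s)\n",
                x$deep$A, x$deep$P, x$deep$K, x$deep$V0,
                if (is.character(x$g_deep_policy)) x$g_deep_policy
                else format(x$g_deep_policy)))
  }
  invisible(x)
}

#' Read gating parameters from a YAML key-value file
#'
#' Accepts either a nested `deep:` mapping or flat dotted keys
#' (`deep.A`, `deep.P`, `deep.K`, `deep.V0`). All voltages in mV.
#'
#' @param path Path to the YAML file.
#' @return A [gating_params()] object.
#' @export
read_gating_params <- function(path) {
  raw <- yaml::read_yaml(path)
  deep <- raw$deep
  flat <- grep("^deep\\.", names(raw), value = TRUE)
  if (is.null(deep) && length(flat)) {
    deep <- setNames(raw[flat], sub("^deep\\.", "", flat))
  }
  gating_params(
    A = raw$A, P = raw$P, K = raw$K, V0 = raw$V0,
    Ro = if (is.null(raw$Ro)) Inf else raw$Ro,
    Rc = if (is.null(raw$Rc)) Inf else raw$Rc,
    tau = if (is.null(raw$tau)) 1 else raw$tau,
    deep = deep,
    g_deep_policy = if (is.null(raw$g_deep_policy)) "closed" else raw$g_deep_policy
  )
}

#' Boltzmann transition probabilities of a two-state subgate
#'
#' With `k = exp(A * P * (V - V0))`, the open->closed probability is
#' `K * k / (1 + k)` and closed->open is `K / (1 + k)`; at `V = V0` both equal
#' `K / 2`. Overflow of the exponential saturates to the limits `K` and `0`.
#'
#' @param params A [gating_params()] object (or its `deep` sub-list wrapped
#'   via `deep_as_params()`).
#' @param V Voltage across the hemichannel, mV (vectorized).
#' @return List with numeric vectors `p_oc`, `p_co`.
#' @export
transition_probabilities <- function(params, V) {
  stopifnot(inherits(params, "gating_params"))
  x <- params$A * params$P * (V - params$V0)
  k <- exp(pmin(x, 700))                     # saturate instead of Inf overflow
  p_oc <- ifelse(x >= 700, params$K, params$K * k / (1 + k))
  p_co <- params$K - p_oc                    # exact complement: p_oc + p_co = K
  list(p_oc = p_oc, p_co = p_co)
}

#' Convert a transition probability to a CTMC rate
#'
#' @param p Transition probability (nonnegative).
#' @param tau Time step, `> 0`.
#' @return `p / tau`, a rate in 1/time.
#' @export
rates_from_probabilities <- function(p, tau) {
  if (any(p < 0)) stop("`p` must be nonnegative.", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be a positive scalar.", call. = FALSE)
  }
  p / tau
}

# Internal: promote the deep-gate parameter set to a gating_params-shaped
# object so transition_probabilities can be reused for c<->d transitions.
deep_as_params <- function(params) {
  d <- params$deep
  if (is.null(d)) stop("Parameter set has no deep-state gate.", call. = FALSE)
  structure(list(A = d$A, P = d$P, K = d$K, V0 = d$V0,
                 Ro = params$Ro, Rc = params$Rc, tau = params$tau,
                 deep = NULL, g_deep_policy = params$g_deep_policy),
            class = "gating_params")
}

#' Rectified open- and closed-state subgate conductances
#'
#' `g_o = 2 * exp(P * V / Ro)` and `g_c = 0.25 * exp(P * V / Rc)`; with
#' `Ro = Rc = Inf` the conductances are the voltage-independent prefactors
#' 2 and 0.25.
#'
#' @inheritParams transition_probabilities
#' @return List with numeric vectors `g_o`, `g_c` (conductance units).
#' @export
subgate_conductances <- function(params, V) {
  stopifnot(inherits(params, "gating_params"))
  g_o <- 2 * exp(pmin(params$P * V / params$Ro, 700))
  g_c <- 0.25 * exp(pmin(params$P * V / params$Rc, 700))
  list(g_o = g_o, g_c = g_c)
}

# Internal: deep-state conductance under the configured policy.
deep_conductance <- function(params, g_c) {
  if (is.character(params$g_deep_policy)) g_c else rep(params$g_deep_policy, length(g_c))
}

#' Hemichannel conductance for a gating state
#'
#' Six subgates conduct in parallel. For two-state hemichannels the state is
#' the number of closed subgates `n_closed` in 0..6 and the conductance is
#' `n_closed * g_c + (6 - n_closed) * g_o`. For three-state hemichannels the
#' state is `c(n_o, n_c)` with `n_o + n_c <= 6`; the remaining
#' `n_d = 6 - n_o - n_c` subgates are deep-closed and contribute `g_d` per the
#' deep-conductance policy.
#'
#' @param state Integer scalar `n_closed` (two-state) or length-2 vector
#'   `c(n_o, n_c)` (three-state).
#' @param params A [gating_params()] object.
#' @param V Voltage across the hemichannel, mV.
#' @return Hemichannel conductance (same units as the subgate conductances).
#' @export
hemichannel_conductance <- function(state, params, V) {
  g <- subgate_conductances(params, V)
  if (length(state) == 1L) {
    if (state < 0 || state > 6) stop("`n_closed` must lie in 0..6.", call. = FALSE)
    state * g$g_c + (6 - state) * g$g_o
  } else if (length(state) == 2L) {
    n_o <- state[1]; n_c <- state[2]
    if (n_o < 0 || n_c < 0 || n_o + n_c > 6) {
      stop("Three-state hemichannel state needs n_o, n_c >= 0 and n_o + n_c <= 6.",
           call. = FALSE)
    }
    n_o * g$g_o + n_c * g$g_c + (6 - n_o - n_c) * deep_conductance(params, g$g_c)
  } else {
    stop("`state` must be n_closed or c(n_o, n_c).", call. = FALSE)
  }
}

# Internal vectorized voltage division across the two serial hemichannels.
#
# g_left_fn / g_right_fn map a vector of voltages-across-the-hemichannel to
# conductances (orientation sign already folded in by the caller). Damped
# fixed-point iteration on V_left = Vj * g_r / (g_l + g_r); a state counts as
# settled when both the relative change of its voltages between consecutive
# iterations and the relative series-current imbalance
# |V_l g_l - V_r g_r| / max(|V_l g_l|, |V_r g_r|) drop below `tol` (0.1%), so
# the returned point satisfies current conservation at the same tolerance.
voltage_division <- function(Vj, g_left_fn, g_right_fn, n,
                             tol = 1e-3, max_iter = 100L, damping = 0.5) {
  if (Vj == 0) {
    z <- rep(0, n)
    gl <- g_left_fn(z); gr <- g_right_fn(z)
    return(list(v_left = z, v_right = z, g_left = gl, g_right = gr,
                iterations = rep(1L, n), converged = rep(TRUE, n)))
  }
  v_l <- rep(Vj / 2, n)
  v_l_prev <- rep(NA_real_, n)
  iters <- rep(NA_integer_, n)
  conv <- rep(FALSE, n)
  denom_floor <- 1e-8 * abs(Vj)
  gl <- gr <- NULL
  for (it in seq_len(max_iter)) {
    v_r <- Vj - v_l
    gl <- g_left_fn(v_l)
    gr <- g_right_fn(v_r)
    i_l <- v_l * gl
    i_r <- v_r * gr
    imbalance <- abs(i_l - i_r) / pmax(pmax(abs(i_l), abs(i_r)), .Machine$double.xmin)
    if (it > 1) {
      rel_l <- abs(v_l - v_l_prev) / pmax(abs(v_l), denom_floor)
      rel_r <- abs(v_l - v_l_prev) / pmax(abs(v_r), denom_floor)
      ok <- rel_l < tol & rel_r < tol & imbalance < tol
      newly <- ok & !conv
      iters[newly] <- it
      conv <- conv | ok
      if (all(conv)) break
    }
    v_l_prev <- v_l
    v_l <- (1 - damping) * v_l + damping * Vj * gr / (gl + gr)
  }
  if (!all(conv)) {
    warning("Voltage division did not converge for every state within the iteration cap.",
            call. = FALSE)
    iters[!conv] <- max_iter
    v_r <- Vj - v_l
    gl <- g_left_fn(v_l)
    gr <- g_right_fn(v_r)
  }
  list(v_left = v_l, v_right = Vj - v_l,
       g_left = gl, g_right = gr,
       iterations = iters, converged = conv)
}

#' Divide the transjunctional voltage across the two hemichannels
#'
#' Solves the series-circuit fixed point
#' `V_left = Vj * g_right / (g_left + g_right)`, `V_right = Vj - V_left`, with
#' both hemichannel conductances evaluated at the returned voltages, by damped
#' fixed-point iteration. Iteration stops when the relative change of both
#' voltages between consecutive iterations falls below 0.1 percent (or the
#' iteration cap is reached, in which case `converged` is `FALSE` and a
#' warning is issued). At the fixed point the series currents balance:
#' `V_left * g_left = V_right * g_right`.
#'
#' The right hemichannel is docked antiparallel to the left one and by default
#' senses the voltage across it with opposite sign (`right_orientation = -1`).
#'
#' @param Vj Transjunctional voltage, mV.
#' @param left_state,right_state Hemichannel gating states as in
#'   [hemichannel_conductance()].
#' @param params_left,params_right [gating_params()] for each hemichannel.
#' @param right_orientation `+1` or `-1`; sign with which the right
#'   hemichannel senses the voltage across it.
#' @param tol Relative convergence tolerance (default 0.1%).
#' @param max_iter Iteration cap.
#' @return List with `v_left`, `v_right` (mV, `v_left + v_right == Vj`),
#'   `g_left`, `g_right`, `iterations`, `converged`.
#' @export
solve_voltage_division <- function(Vj, left_state, right_state,
                                   params_left, params_right,
                                   right_orientation = -1,
                                   tol = 1e-3, max_iter = 100L) {
  stopifnot(is.finite(Vj))
  gl_fn <- function(v) hemichannel_conductance(left_state, params_left, v)
  gr_fn <- function(v) hemichannel_conductance(right_state, params_right,
                                               right_orientation * v)
  res <- voltage_division(Vj, gl_fn, gr_fn, n = 1L, tol = tol,
                          max_iter = as.integer(max_iter))
  lapply(res, function(x) x[[1]])
}

#' Steady-state junctional conductance
#'
#' Probability-weighted series conductance over all global gating states:
#' `g_j = sum_i pi_i * g_left_i * g_right_i / (g_left_i + g_right_i)`, with
#' each state's hemichannel conductances evaluated at that state's voltage
#' split. States where both conductances vanish contribute 0.
#'
#' @param pi Steady-state probability vector (sums to 1 within 1e-9).
#' @param generator A [build_generator()] result carrying the per-state
#'   voltage-split cache, or a data frame with columns `g_left`, `g_right`.
#' @return Junctional conductance `g_j` (scalar).
#' @export
junction_conductance <- function(pi, generator) {
  splits <- if (inherits(generator, "gj_generator")) generator$vsplits else
    as.data.frame(generator)
  if (abs(sum(pi) - 1) > 1e-9) {
    stop("`pi` must sum to 1 (within 1e-9).", call. = FALSE)
  }
  if (length(pi) != nrow(splits)) {
    stop("`pi` length does not match the state space.", call. = FALSE)
  }
  gl <- splits$g_left; gr <- splits$g_right
  denom <- gl + gr
  term <- ifelse(denom > 0, gl * gr / denom, 0)
  sum(pi * term)
}
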