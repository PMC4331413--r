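#' Kronecker product of two matrices
#'
#' Thin validated wrapper around the base Kronecker product: block `(i, j)` of
#' the result equals `a_ij * B`.
#'
#' @param A,B Numeric matrices (non-empty).
#' @return A numeric matrix of dimension `(m*p) x (n*q)`.
#' @examples
#' kron_product(diag(2), diag(2))   # identity of size 4
#' @export
kron_product <- function(A, B) {
  A <- as_nonempty_matrix(A, "A")
  B <- as_nonempty_matrix(B, "B")
  kronecker(A, B)
}

#' Kronecker (tensor) sum of two square matrices
#'
#' `A %kron-sum% B = A (x) I_n + I_m (x) B`. For infinitesimal generators of
#' two independent automata this is the generator of the joint process, with
#' the first operand as the slow index.
#'
#' @param A,B Square numeric matrices.
#' @return A square numeric matrix of dimension `m*n`.
#' @examples
#' Q <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
#' kron_sum(Q, Q)
#' @export
kron_sum <- function(A, B) {
  A <- as_nonempty_matrix(A, "A")
  B <- as_nonempty_matrix(B, "B")
  if (nrow(A) != ncol(A)) stop("`A` must be square for a Kronecker sum.", call. = FALSE)
  if (nrow(B) != ncol(B)) stop("`B` must be square for a Kronecker sum.", call. = FALSE)
  kronecker(A, diag(nrow(B))) + kronecker(diag(nrow(A)), B)
}

#' Define a local automaton
#'
#' A local automaton is a small Markov chain: a state count and a transition
#' list. Transition rates are referenced by opaque labels and resolved at
#' composition time by a rate function, so the tensor layer stays free of
#' biophysics. A `mult` column carries combinatorial multiplicities (e.g. the
#' number of identical subgates able to make the move).
#'
#' @param n_states Positive integer number of local states.
#' @param transitions Data frame with columns `from`, `to` (1-based local state
#'   indices, `from != to`), `label` (character) and optionally `mult`
#'   (nonnegative numeric multiplicity, default 1).
#' @return An object of class `local_automaton`.
#' @export
local_automaton <- function(n_states, transitions) {
  stopifnot(is.numeric(n_states), length(n_states) == 1L, n_states >= 1)
  n_states <- as.integer(n_states)
  transitions <- as.data.frame(transitions)
  req <- c("from", "to", "label")
  if (!all(req %in% names(transitions))) {
    stop("`transitions` needs columns from, to, label.", call. = FALSE)
  }
  if (is.null(transitions$mult)) transitions$mult <- 1
  with(transitions, {
    if (any(from < 1L | from > n_states | to < 1L | to > n_states)) {
      stop("Transition indices out of range.", call. = FALSE)
    }
    if (any(from == to)) {
      stop("Self-transitions are not listed; the diagonal is derived.", call. = FALSE)
    }
    if (any(mult < 0)) stop("Multiplicities must be nonnegative.", call. = FALSE)
  })
  structure(list(n_states = n_states, transitions = transitions),
            class = "local_automaton")
}

#' Enumerate the product state space of a list of automata
#'
#' Global states are ordered lexicographically with the FIRST automaton as the
#' slow index, matching the block layout of generators composed by Kronecker
#' sums.
#'
#' @param automata List of [local_automaton()] objects.
#' @return Integer matrix with one row per global state and one column per
#'   automaton, holding 1-based local state indices.
#' @keywords internal
product_states <- function(automata) {
  ns <- vapply(automata, function(a) a$n_states, integer(1))
  grids <- rev(lapply(ns, seq_len))
  g <- as.matrix(rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Compose a global generator with state-dependent (functional) rates
#'
#' Generalized Kronecker-sum composition: each local transition contributes an
#' off-diagonal entry whose rate may depend on the *global* state. With a
#' constant rate function the result coincides with the ordinary Kronecker sum
#' of the local generators. Diagonal entries are the negated row sums.
#'
#' @param automata List of [local_automaton()] objects.
#' @param rates Function `(label, automaton, state_rows) -> numeric vector` of
#'   nonnegative rates, vectorized over `state_rows` (global state row
#'   indices into the product enumeration).
#' @param ordering Optional integer matrix as produced by `product_states()`;
#'   must enumerate the full product space in the same order (supplied by
#'   callers that also need the enumeration, avoids recomputation).
#' @return Square numeric matrix: the global infinitesimal generator.
#' @export
assemble_functional_generator <- function(automata, rates, ordering = NULL) {
  if (!length(automata)) stop("Need at least one automaton.", call. = FALSE)
  states <- if (is.null(ordering)) product_states(automata) else ordering
  ns <- vapply(automata, function(a) a$n_states, integer(1))
  N <- prod(ns)
  if (nrow(states) != N) {
    stop("`ordering` does not enumerate the full product state space.", call. = FALSE)
  }
  # column stride of automaton a in the mixed-radix index (first automaton slow)
  strides <- rev(cumprod(rev(c(ns[-1], 1L))))
  Q <- matrix(0, N, N)
  for (a in seq_along(automata)) {
    tr <- automata[[a]]$transitions
    for (t in seq_len(nrow(tr))) {
      rows <- which(states[, a] == tr$from[t])
      if (!length(rows)) next
      cols <- rows + (tr$to[t] - tr$from[t]) * strides[a]
      r <- rates(tr$label[t], a, rows)
      bad <- !is.finite(r) | r < 0
      if (any(bad)) {
        stop(sprintf(
          "Rate function returned a negative or non-finite value for label '%s' at global state %d.",
          tr$label[t], rows[which(bad)[1]]), call. = FALSE)
      }
      Q[cbind(rows, cols)] <- Q[cbind(rows, cols)] + tr$mult[t] * r
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Constant-rate function for [assemble_functional_generator()]
#'
#' @param rate_table Named numeric vector mapping rate labels to constants.
#' @return A rate function usable with [assemble_functional_generator()].
#' @export
constant_rates <- function(rate_table) {
  force(rate_table)
  function(label, automaton, state_rows) {
    r <- rate_table[[label]]
    if (is.null(r)) stop(sprintf("No rate for label '%s'.", label), call. = FALSE)
    rep(r, length(state_rows))
  }
}

#' Half-bandwidths and bandwidth of a square matrix
#'
#' `k1` (`k2`) is the smallest left (right) half-bandwidth such that all
#' entries with `j < i - k1` or `j > i + k2` vanish; the bandwidth is
#' `m = k1 + k2 + 1` (a tridiagonal matrix has `m = 3`).
#'
#' @param Q Square numeric matrix.
#' @return Named list with integers `k1`, `k2`, `m`.
#' @examples
#' matrix_bandwidth(diag(3))  # k1 = k2 = 0, m = 1
#' @export
matrix_bandwidth <- function(Q) {
  Q <- as_nonempty_matrix(Q, "Q")
  if (nrow(Q) != ncol(Q)) stop("`Q` must be square.", call. = FALSE)
  nz <- which(Q != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(list(k1 = 0L, k2 = 0L, m = 1L))
  d <- nz[, "row"] - nz[, "col"]
  k1 <- max(0L, max(d))
  k2 <- max(0L, -min(d))
  list(k1 = as.integer(k1), k2 = as.integer(k2), m = as.integer(k1 + k2 + 1L))
}

as_nonempty_matrix <- function(x, name) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) == 0L || ncol(x) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric matrix.", name), call. = FALSE)
  }
  x
}
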