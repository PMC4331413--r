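#' Options for the iterative steady-state solvers
#'
#' @param epsilon Convergence tolerance: a sweep converges when all entries of
#'   consecutive iterates differ by less than `epsilon` in absolute value.
#' @param max_outer_iterations Outer-iteration cap.
#' @param initial_vector Optional starting probability vector (nonnegative,
#'   sums to 1 within 1e-9); the default is the uniform vector `1/n`.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(epsilon = 1e-6, max_outer_iterations = 10000L,
                           initial_vector = NULL) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            max_outer_iterations >= 1)
  if (!is.null(initial_vector)) {
    if (any(initial_vector < 0) || abs(sum(initial_vector) - 1) > 1e-9) {
      stop("`initial_vector` must be nonnegative and sum to 1.", call. = FALSE)
    }
  }
  structure(list(epsilon = epsilon,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 initial_vector = initial_vector),
            class = "solver_options")
}

#' Entrywise convergence check for iterative solvers
#'
#' `TRUE` iff the maximum absolute entrywise difference between consecutive
#' iterates is below `epsilon`.
#'
#' @param pi_new,pi_old Numeric vectors of equal length.
#' @param epsilon Positive tolerance.
#' @return Logical scalar.
#' @export
convergence_check <- function(pi_new, pi_old, epsilon) {
  if (length(pi_new) != length(pi_old)) {
    stop("Iterates must have equal length.", call. = FALSE)
  }
  max(abs(pi_new - pi_old)) < epsilon
}

new_solver_result <- function(pi, method, outer_iterations, residual, converged,
                              residual_history = NULL) {
  if (any(pi < -1e-12)) {
    stop("Solver produced a substantially negative probability.", call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-10) {
    stop("Solver result does not sum to 1.", call. = FALSE)
  }
  structure(list(pi = pi, method = method,
                 outer_iterations = as.integer(outer_iterations),
                 residual = residual, converged = converged,
                 residual_history = residual_history),
            class = "gj_steady_state")
}

#' @export
print.gj_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): n = %d, outer iterations = %d, residual = %.3e, converged = %s\n",
              x$method, length(x$pi), x$outer_iterations, x$residual, x$converged))
  invisible(x)
}

generator_matrix <- function(Q) {
  if (inherits(Q, "gj_generator")) Q$Q else as_nonempty_matrix(Q, "Q")
}

#' Steady state by dense Gaussian elimination
#'
#' Solves the transposed balance system with the last equation replaced by the
#' normalization constraint `sum(pi) = 1`.
#'
#' @param Q Infinitesimal generator (matrix or [build_generator()] result) of
#'   an irreducible chain.
#' @return A `gj_steady_state` with `outer_iterations = 0`.
#' @export
solve_dense <- function(Q) {
  Qm <- generator_matrix(Q)
  n <- nrow(Qm)
  M <- t(Qm)
  M[n, ] <- 1
  rhs <- c(rep(0, n - 1), 1)
  pi <- tryCatch(as.numeric(solve(M, rhs)),
                 error = function(e) {
                   stop("Singular beyond rank one: the chain appears reducible.",
                        call. = FALSE)
                 })
  pi <- pi / sum(pi)
  new_solver_result(pi, "dense_ge", 0L, max(abs(pi %*% Qm)), TRUE)
}

# Internal: banded LU with partial pivoting on dense storage. Solves A x = b
# for A with left half-bandwidth kl and right half-bandwidth ku; pivoting
# widens the upper band to kl + ku.
banded_lu_solve <- function(A, b, kl, ku) {
  n <- nrow(A)
  x <- as.numeric(b)
  kw <- kl + ku
  if (n > 1) {
    for (j in 1:(n - 1)) {
      rmax <- min(j + kl, n)
      piv <- which.max(abs(A[j:rmax, j])) + j - 1L
      if (abs(A[piv, j]) < .Machine$double.xmin) {
        stop("Banded factorization hit a zero pivot (singular system).", call. = FALSE)
      }
      cmax <- min(j + kw, n)
      if (piv != j) {
        tmp <- A[j, j:cmax]; A[j, j:cmax] <- A[piv, j:cmax]; A[piv, j:cmax] <- tmp
        tmp <- x[j]; x[j] <- x[piv]; x[piv] <- tmp
      }
      if (rmax > j) {
        rows <- (j + 1):rmax
        mult <- A[rows, j] / A[j, j]
        A[rows, j:cmax] <- A[rows, j:cmax] - outer(mult, A[j, j:cmax])
        x[rows] <- x[rows] - mult * x[j]
      }
    }
  }
  for (i in n:1) {
    cmax <- min(i + kw, n)
    if (cmax > i) x[i] <- x[i] - sum(A[i, (i + 1):cmax] * x[(i + 1):cmax])
    x[i] <- x[i] / A[i, i]
  }
  x
}

#' Steady state by banded Gaussian elimination
#'
#' Exploits the banded structure of the generator: the last state's
#' probability is grounded to 1, the leading principal banded subsystem of the
#' transposed balance equations is solved by banded LU with partial pivoting
#' (which preserves the band up to the usual `k1 + k2` upper fill), and the
#' solution is renormalized.
#'
#' @inheritParams solve_dense
#' @param k1,k2 Left/right half-bandwidths of `Q`; defaults to the generator's
#'   stored or measured bandwidth. Supplying a band too narrow to contain all
#'   nonzeros is an error.
#' @return A `gj_steady_state` with `outer_iterations = 0`.
#' @export
solve_banded <- function(Q, k1 = NULL, k2 = NULL) {
  Qm <- generator_matrix(Q)
  bw <- if (inherits(Q, "gj_generator")) Q$bandwidth else matrix_bandwidth(Qm)
  if (is.null(k1)) k1 <- bw$k1
  if (is.null(k2)) k2 <- bw$k2
  meas <- matrix_bandwidth(Qm)
  if (k1 < meas$k1 || k2 < meas$k2) {
    stop(sprintf("Invalid band: nonzeros outside the supplied band (need k1 >= %d, k2 >= %d).",
                 meas$k1, meas$k2), call. = FALSE)
  }
  n <- nrow(Qm)
  Qt <- t(Qm)                                     # half-bandwidths swap
  y <- banded_lu_solve(Qt[-n, -n, drop = FALSE], -Qt[-n, n], kl = k2, ku = k1)
  pi <- c(y, 1)
  pi <- pi / sum(pi)
  new_solver_result(pi, "banded_ge", 0L, max(abs(pi %*% Qm)), TRUE)
}

block_offsets <- function(block_sizes) cumsum(c(0L, block_sizes[-length(block_sizes)]))

block_index <- function(block_sizes, i) {
  off <- block_offsets(block_sizes)
  (off[i] + 1):(off[i] + block_sizes[i])
}

# Internal: validate block-tridiagonal structure (zero outside adjacent blocks)
is_block_tridiagonal <- function(Q, block_sizes) {
  N <- length(block_sizes)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (abs(i - j) <= 1) next
      if (any(Q[block_index(block_sizes, i), block_index(block_sizes, j)] != 0)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Steady state by the block recursive direct method
#'
#' Direct solution for block-tridiagonal generators with equal block sizes
#' whose off-diagonal blocks are diagonal matrices (the 12 two-state-subgate
#' model). The generator is partitioned into its first block column `V`, the
#' block lower-triangular remainder `W` (whose diagonal blocks are the
#' diagonal super-diagonal blocks of the generator and hence trivially
#' invertible), and the last block row; a forward substitution computes
#' `Z = W^-1 V`, a small dense solve fixes the last probability segment from
#' the reduced singular system, and a backward substitution recovers the rest,
#' followed by global normalization.
#'
#' @param G A [build_generator()] result (or list with elements `Q` and
#'   `block_sizes`). Varying block sizes raise an unsupported-structure error,
#'   mirroring the method's domain of applicability.
#' @return A `gj_steady_state` with `outer_iterations = 0`.
#' @export
solve_block_recursive <- function(G) {
  if (inherits(G, "gj_generator")) {
    Q <- G$Q; bs <- G$block_sizes
  } else {
    Q <- as_nonempty_matrix(G$Q, "G$Q"); bs <- as.integer(G$block_sizes)
  }
  N <- length(bs)
  if (N < 2) stop("Need at least two diagonal blocks.", call. = FALSE)
  if (length(unique(bs)) != 1L) {
    stop("Unsupported structure: the block recursive method requires equal block sizes.",
         call. = FALSE)
  }
  if (!is_block_tridiagonal(Q, bs)) {
    stop("Unsupported structure: generator is not block tridiagonal.", call. = FALSE)
  }
  nb <- bs[1]
  blk <- function(i, j) Q[block_index(bs, i), block_index(bs, j), drop = FALSE]
  # super-diagonal blocks must be invertible diagonal matrices
  supers <- lapply(seq_len(N - 1), function(i) blk(i, i + 1))
  for (S in supers) {
    if (max(abs(S - diag(diag(S), nb))) > 0 || any(diag(S) == 0)) {
      stop("Unsupported structure: super-diagonal blocks must be invertible diagonal matrices.",
           call. = FALSE)
    }
  }

  # forward substitution: Z_i = W[i,i]^-1 (V_i - Q_ii Z_{i-1} - Q_{i,i-1} Z_{i-2})
  Z <- vector("list", N - 1)
  for (i in seq_len(N - 1)) {
    Vi <- if (i == 1) blk(1, 1) else if (i == 2) blk(2, 1) else matrix(0, nb, nb)
    acc <- Vi
    if (i >= 2) acc <- acc - blk(i, i) %*% Z[[i - 1]]
    if (i >= 3) acc <- acc - blk(i, i - 1) %*% Z[[i - 2]]
    Z[[i]] <- acc / diag(supers[[i]])            # rowwise division by the diagonal
  }

  # reduced singular system for the last segment: pi_N (X - Y W^-1 V) = 0
  X <- if (N == 2) blk(2, 1) else matrix(0, nb, nb)
  M <- X - blk(N, N) %*% Z[[N - 1]]
  if (N >= 3) M <- M - blk(N, N - 1) %*% Z[[N - 2]]
  MM <- t(M)
  MM[nb, ] <- 1
  pi_N <- as.numeric(solve(MM, c(rep(0, nb - 1), 1)))

  # backward substitution: pi_* W = -pi_N Y
  segs <- vector("list", N)
  segs[[N]] <- pi_N
  cvec <- function(j) {                          # c_j = -pi_N Q_{N, j+1}
    if (j == N - 1) -as.numeric(pi_N %*% blk(N, N)) else
    if (j == N - 2) -as.numeric(pi_N %*% blk(N, N - 1)) else rep(0, nb)
  }
  for (j in (N - 1):1) {
    acc <- cvec(j)
    if (j + 1 <= N - 1) acc <- acc - as.numeric(segs[[j + 1]] %*% blk(j + 1, j + 1))
    if (j + 2 <= N - 1) acc <- acc - as.numeric(segs[[j + 2]] %*% blk(j + 2, j + 1))
    segs[[j]] <- acc / diag(supers[[j]])
  }
  pi <- unlist(segs)
  pi <- pi / sum(pi)
  new_solver_result(pi, "block_recursive", 0L, max(abs(pi %*% Q)), TRUE)
}

# Internal: solve the row-vector system x T = b for tridiagonal T via the
# Thomas algorithm applied to t(T) x' = b'.
thomas_solve_left <- function(T, b) {
  A <- t(T)
  n <- nrow(A)
  if (n == 1) return(b / A[1, 1])
  d <- diag(A)
  dl <- A[cbind(2:n, 1:(n - 1))]       # sub-diagonal of t(T)
  du <- A[cbind(1:(n - 1), 2:n)]       # super-diagonal of t(T)
  x <- as.numeric(b)
  for (i in 2:n) {
    w <- dl[i - 1] / d[i - 1]
    d[i] <- d[i] - w * du[i - 1]
    x[i] <- x[i] - w * x[i - 1]
  }
  x[n] <- x[n] / d[n]
  for (i in (n - 1):1) x[i] <- (x[i] - du[i] * x[i + 1]) / d[i]
  x
}

#' Steady state by warm-startable block Gauss-Seidel
#'
#' Sweeps the diagonal blocks in index order; for each block the inner system
#' against the diagonal block is solved by the Thomas algorithm when the block
#' is tridiagonal and by banded LU otherwise (the 12 three-state-subgate
#' model's 28x28 diagonal blocks). The iterate is renormalized to sum 1 after
#' each outer sweep; iteration stops when all entries of consecutive iterates
#' differ by less than `epsilon` or the cap is reached.
#'
#' @param G A [build_generator()] result (or list with `Q` and `block_sizes`).
#' @param options A [solver_options()] object; `initial_vector` enables warm
#'   starts.
#' @return A `gj_steady_state` with the outer-iteration count, the final
#'   max-norm residual of `pi Q`, and the per-sweep residual history.
#' @export
solve_block_gauss_seidel <- function(G, options = solver_options()) {
  if (inherits(G, "gj_generator")) {
    Q <- G$Q; bs <- G$block_sizes
  } else {
    Q <- as_nonempty_matrix(G$Q, "G$Q"); bs <- as.integer(G$block_sizes)
  }
  stopifnot(inherits(options, "solver_options"))
  n <- nrow(Q)
  N <- length(bs)
  idx <- lapply(seq_len(N), function(i) block_index(bs, i))
  diag_blocks <- lapply(idx, function(ii) Q[ii, ii, drop = FALSE])
  solvers <- lapply(diag_blocks, function(D) {
    bwD <- matrix_bandwidth(D)
    if (bwD$k1 <= 1 && bwD$k2 <= 1) {
      function(b) thomas_solve_left(D, b)
    } else {
      Dt <- t(D)
      function(b) banded_lu_solve(Dt, b, kl = bwD$k2, ku = bwD$k1)
    }
  })

  pi <- if (is.null(options$initial_vector)) rep(1 / n, n) else {
    if (length(options$initial_vector) != n) {
      stop("`initial_vector` has the wrong length.", call. = FALSE)
    }
    as.numeric(options$initial_vector)
  }
  residual_history <- numeric(0)
  converged <- FALSE
  outer <- 0L
  for (k in seq_len(options$max_outer_iterations)) {
    outer <- k
    pi_old <- pi
    for (i in seq_len(N)) {
      cols <- idx[[i]]
      full <- as.numeric(pi %*% Q[, cols, drop = FALSE])
      own <- as.numeric(pi[cols] %*% diag_blocks[[i]])
      pi[cols] <- solvers[[i]](own - full)
    }
    pi <- pi / sum(pi)
    residual_history[k] <- max(abs(pi %*% Q))
    if (convergence_check(pi, pi_old, options$epsilon)) {
      converged <- TRUE
      break
    }
  }
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  if (!converged) {
    warning(sprintf("Block Gauss-Seidel did not converge in %d outer iterations (last residual %.3e).",
                    outer, residual_history[length(residual_history)]), call. = FALSE)
  }
  new_solver_result(pi, "block_gauss_seidel", outer,
                    residual_history[length(residual_history)], converged,
                    residual_history = residual_history)
}

#' Solve for the steady state with a selectable method
#'
#' Unified front end over the four solvers.
#'
#' @param G A [build_generator()] result (direct matrix input is accepted for
#'   the dense and banded methods).
#' @param method One of `"dense_ge"`, `"banded_ge"`, `"block_recursive"`,
#'   `"block_gauss_seidel"`.
#' @param options A [solver_options()] (iterative methods only).
#' @return A `gj_steady_state`.
#' @export
solve_steady_state <- function(G, method = c("dense_ge", "banded_ge",
                                             "block_recursive",
                                             "block_gauss_seidel"),
                               options = solver_options()) {
  method <- match.arg(method)
  switch(method,
    dense_ge = solve_dense(G),
    banded_ge = solve_banded(G),
    block_recursive = solve_block_recursive(G),
    block_gauss_seidel = solve_block_gauss_seidel(G, options))
}

# Internal: strong-connectivity check of the transition graph.
is_irreducible <- function(Q) {
  n <- nrow(Q)
  adj <- Q > 0
  reach <- function(A) {
    seen <- logical(n); seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

#' Group inverse of an irreducible infinitesimal generator
#'
#' Computes `Q# = (Q - e pi)^-1 + e pi`, where `pi` is the stationary row
#' vector and `e` the all-ones column. The result satisfies the defining
#' identities `Q Q# Q = Q`, `Q# Q Q# = Q#`, `Q Q# = Q# Q = I - e pi`, and
#' drives the steady-state perturbation bound
#' `||delta pi|| / ||pi|| <= ||Q#|| * ||delta Q||` (vector 1-norm, matrix
#' infinity-norm).
#'
#' @inheritParams solve_dense
#' @return The group inverse matrix.
#' @export
group_inverse <- function(Q) {
  Qm <- generator_matrix(Q)
  if (!is_irreducible(Qm)) {
    stop("Group inverse requires an irreducible chain.", call. = FALSE)
  }
  pi <- solve_dense(Qm)$pi
  n <- nrow(Qm)
  epi <- matrix(1, n, 1) %*% matrix(pi, 1, n)
  solve(Qm - epi) + epi
}
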