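#' Configure a transjunctional-voltage sweep
#'
#' @param model_kind Model selector as in [enumerate_states()].
#' @param params_left,params_right [gating_params()] for the two hemichannels.
#' @param v_start,v_end,v_step Voltage grid, mV; `v_step > 0` and the grid
#'   must land on `v_end` within rounding (1e-9).
#' @param method Solver selector as in [solve_steady_state()].
#' @param epsilon Convergence tolerance for the iterative solver.
#' @param warm_start If `TRUE` ("Method II"), each iterative solve is seeded
#'   with the previous grid point's solution whenever the voltage increment is
#'   at most 1 mV; otherwise ("Method I") every solve starts from the uniform
#'   vector.
#' @param max_outer_iterations Outer-iteration cap per solve.
#' @param seed Integer seed recorded with the configuration (used by fixture
#'   generation workflows).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(model_kind, params_left, params_right = params_left,
                         v_start = 0, v_end = 100, v_step = 0.1,
                         method = "block_gauss_seidel", epsilon = 1e-6,
                         warm_start = TRUE, max_outer_iterations = 10000L,
                         seed = NULL) {
  model_kind <- match.arg(model_kind,
                          c("two_state_12", "three_state_6", "three_state_12"))
  method <- match.arg(method, c("dense_ge", "banded_ge", "block_recursive",
                                "block_gauss_seidel"))
  stopifnot(inherits(params_left, "gating_params"),
            inherits(params_right, "gating_params"),
            v_step > 0, is.finite(v_start), is.finite(v_end), v_end >= v_start)
  steps <- (v_end - v_start) / v_step
  if (abs(steps - round(steps)) > 1e-9) {
    stop("(v_end - v_start) / v_step must be an integer (within 1e-9).", call. = FALSE)
  }
  structure(list(model_kind = model_kind, params_left = params_left,
                 params_right = params_right, v_start = v_start, v_end = v_end,
                 v_step = v_step, method = method, epsilon = epsilon,
                 warm_start = isTRUE(warm_start),
                 max_outer_iterations = as.integer(max_outer_iterations),
                 seed = seed),
            class = "sweep_config")
}

#' Run a voltage sweep and compute the g_j-V_j curve
#'
#' For each voltage on the grid, builds the model generator, solves for the
#' steady state, and evaluates the junctional conductance as the
#' probability-weighted series conductance over the per-state voltage splits.
#' With `warm_start = TRUE` the iterative solver is seeded with the previous
#' grid point's solution when the voltage increment is small (<= 1 mV);
#' otherwise every solve starts cold from the uniform vector. Non-converged
#' solves are recorded and the sweep continues.
#'
#' @param config A [sweep_config()].
#' @return An object of class `gj_sweep`: list with `records` (tibble with
#'   columns `vj_mv`, `gj`, `gj_normalized`, `outer_iterations`, `residual`,
#'   `converged`), `total_outer_iterations`, `all_converged`, and `config`.
#'   `gj_normalized` is `gj` divided by its value at the grid point nearest
#'   0 mV.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- config$v_start + config$v_step * 0:round((config$v_end - config$v_start) / config$v_step)
  n_pts <- length(grid)
  gj <- iters <- resid <- numeric(n_pts)
  conv <- logical(n_pts)
  prev_pi <- NULL
  prev_v <- NA_real_
  iterative <- config$method == "block_gauss_seidel"
  for (i in seq_len(n_pts)) {
    gen <- build_generator(config$model_kind, config$params_left,
                           config$params_right, vj = grid[i])
    init <- NULL
    if (iterative && config$warm_start && !is.null(prev_pi) &&
        abs(grid[i] - prev_v) <= 1 + 1e-12) {
      init <- prev_pi
    }
    res <- solve_steady_state(gen, config$method,
                              solver_options(epsilon = config$epsilon,
                                             max_outer_iterations = config$max_outer_iterations,
                                             initial_vector = init))
    gj[i] <- junction_conductance(res$pi, gen)
    iters[i] <- res$outer_iterations
    resid[i] <- res$residual
    conv[i] <- res$converged
    if (res$converged) {
      prev_pi <- res$pi
      prev_v <- grid[i]
    }
  }
  ref <- which.min(abs(grid))
  records <- tibble::tibble(vj_mv = grid, gj = gj,
                            gj_normalized = gj / gj[ref],
                            outer_iterations = as.integer(iters),
                            residual = resid, converged = conv)
  structure(list(records = records,
                 total_outer_iterations = sum(iters),
                 all_converged = all(conv),
                 config = config),
            class = "gj_sweep")
}

#' @export
print.gj_sweep <- function(x, ...) {
  cat(sprintf("Voltage sweep '%s' (%s%s): %d points, %g..%g mV\n",
              x$config$model_kind, x$config$method,
              if (x$config$method == "block_gauss_seidel")
                sprintf(", %s", if (x$config$warm_start) "warm start" else "cold start")
              else "",
              nrow(x$records), x$config$v_start, x$config$v_end))
  cat(sprintf("  total outer iterations: %d; all converged: %s\n",
              x$total_outer_iterations, x$all_converged))
  print(head(x$records, 5))
  invisible(x)
}

#' Generate a reproducible synthetic gating-parameter pair
#'
#' Draws a homotypic (or heterotypic) pair of parameter sets in realistic
#' ranges: `A` uniform in 0.01..0.1 /mV, `V0` in 10..60 mV, `K` in
#' 0.002..0.02 with `tau = 1` so that transition rates land around the
#' 0.001-0.01 magnitude typical of these models, mild rectification
#' (`Ro`, `Rc` in 100..500 mV), and an independent deep-gate parameter set of
#' the same form. The global RNG state is restored on exit; identical seeds
#' give identical parameter sets.
#'
#' @param seed Integer seed.
#' @param homotypic If `TRUE` (default) the right hemichannel gets a copy of
#'   the left parameter set; otherwise an independent draw.
#' @return List with elements `left` and `right`, both [gating_params()].
#' @export
generate_fixture_params <- function(seed, homotypic = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  draw <- function() {
    gating_params(
      A = runif(1, 0.01, 0.1), P = 1,
      K = runif(1, 0.002, 0.02), V0 = runif(1, 10, 60),
      Ro = runif(1, 100, 500), Rc = runif(1, 100, 500), tau = 1,
      deep = list(A = runif(1, 0.01, 0.05), P = 1,
                  K = runif(1, 0.002, 0.02), V0 = runif(1, 20, 60)))
  }
  left <- draw()
  list(left = left, right = if (homotypic) left else draw())
}

#' Write sweep results to CSV or JSON
#'
#' CSV columns are exactly `vj_mv, gj, gj_normalized, outer_iterations,
#' residual, converged`; JSON mirrors the record structure together with the
#' sweep totals. Values round-trip at full double precision.
#'
#' @param result A [run_sweep()] result (or a bare records data frame).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- if (inherits(result, "gj_sweep")) result$records else
    tibble::as_tibble(result)
  cols <- c("vj_mv", "gj", "gj_normalized", "outer_iterations", "residual",
            "converged")
  if (!all(cols %in% names(records))) {
    stop("Records must have columns: ", paste(cols, collapse = ", "), call. = FALSE)
  }
  records <- records[cols]
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    # full double precision for the round trip
    df <- as.data.frame(records)
    for (nm in c("vj_mv", "gj", "gj_normalized", "residual")) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(records = records)
    if (inherits(result, "gj_sweep")) {
      payload$total_outer_iterations <- result$total_outer_iterations
      payload$all_converged <- result$all_converged
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read sweep results written by [write_results()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`.
#' @return A tibble of sweep records.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path)
    df$converged <- as.logical(df$converged)
    df$outer_iterations <- as.integer(df$outer_iterations)
    tibble::as_tibble(df)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    tibble::as_tibble(raw$records)
  }
}
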