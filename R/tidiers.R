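#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state solution into a tibble
#'
#' @param x A `gj_steady_state`.
#' @param generator Optional [build_generator()] result; when supplied, the
#'   model's state labels are attached.
#' @param ... Unused.
#' @return A tibble with one row per global state.
#' @method tidy gj_steady_state
#' @export
tidy.gj_steady_state <- function(x, generator = NULL, ...) {
  out <- tibble::tibble(state = seq_along(x$pi), probability = x$pi)
  if (!is.null(generator) && inherits(generator, "gj_generator")) {
    out <- tibble::as_tibble(cbind(out, generator$state_space$states))
  }
  out
}

#' One-row summary of a steady-state solve
#'
#' @param x A `gj_steady_state`.
#' @param ... Unused.
#' @return A one-row tibble with method, size and convergence diagnostics.
#' @method glance gj_steady_state
#' @export
glance.gj_steady_state <- function(x, ...) {
  tibble::tibble(method = x$method, n = length(x$pi),
                 outer_iterations = x$outer_iterations,
                 residual = x$residual, converged = x$converged)
}

#' Tidy a voltage sweep into its per-voltage records
#'
#' @param x A `gj_sweep`.
#' @param ... Unused.
#' @return The records tibble.
#' @method tidy gj_sweep
#' @export
tidy.gj_sweep <- function(x, ...) x$records

#' One-row summary of a voltage sweep
#'
#' @param x A `gj_sweep`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance gj_sweep
#' @export
glance.gj_sweep <- function(x, ...) {
  tibble::tibble(model = x$config$model_kind, method = x$config$method,
                 warm_start = x$config$warm_start,
                 n_voltages = nrow(x$records),
                 total_outer_iterations = x$total_outer_iterations,
                 all_converged = x$all_converged,
                 gj_min_normalized = min(x$records$gj_normalized))
}

#' Plot the normalized g_j-V_j curve of a sweep
#'
#' @param object A `gj_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gj_sweep
#' @export
autoplot.gj_sweep <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$vj_mv, y = .data$gj_normalized)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Transjunctional voltage (mV)",
                  y = "Normalized junctional conductance",
                  title = sprintf("Steady-state gating curve, %s",
                                  object$config$model_kind)) +
    ggplot2::theme_minimal()
}

#' Plot the sparsity pattern of a generator
#'
#' @param object A `gj_generator`.
#' @param ... Unused.
#' @return A ggplot object showing the nonzero entries.
#' @method autoplot gj_generator
#' @export
autoplot.gj_generator <- function(object, ...) {
  nz <- which(object$Q != 0, arr.ind = TRUE)
  df <- tibble::tibble(row = nz[, "row"], col = nz[, "col"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_point(shape = 15, size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Nonzero structure of '%s' generator (n = %d, m = %d)",
                                  object$kind, object$state_space$n,
                                  object$bandwidth$m)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
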