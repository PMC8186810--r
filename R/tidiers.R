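# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a training run into a long tibble of per-epoch metrics
#'
#' @param x an `rnn_fit` from [train_network()].
#' @param ... unused.
#' @return a tibble with columns `epoch`, `split`, `metric`, `value`.
#' @export
tidy.rnn_fit <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x an `rnn_fit`.
#' @param ... unused.
#' @return a one-row tibble: cell, layer sizes, parameter count, epochs,
#'   final metrics, divergence flag.
#' @export
glance.rnn_fit <- function(x, ...) {
  out <- tibble::tibble(
    cell = x$model$cell,
    hidden = paste(x$model$hidden, collapse = "x"),
    n_params = n_params(x$model),
    epochs = x$config$epochs,
    diverged = x$diverged
  )
  for (nm in names(x$metrics)) out[[nm]] <- unname(x$metrics[nm])
  out
}

#' @export
tidy.protocol_result <- function(x, ...) x$per_seed

#' @export
glance.protocol_result <- function(x, ...) {
  out <- tibble::tibble(
    cell = x$config$cell,
    hidden = paste(x$config$hidden, collapse = "x"),
    n_seeds = length(x$config$seeds),
    epochs = x$config$epochs
  )
  for (i in seq_len(nrow(x$summary))) {
    out[[paste0(x$summary$metric[i], "_mean")]] <- x$summary$mean[i]
    out[[paste0(x$summary$metric[i], "_sd")]] <- x$summary$sd[i]
  }
  out
}

#' Tidy a fixed-point set or an unrolled state trajectory
#'
#' @param x a `"fixed_points"` tibble or an `"rnn_trace"` from [unroll()].
#' @param ... unused.
#' @return a tibble (for traces: `layer`, `step`, `neuron`, `h`).
#' @export
tidy.rnn_trace <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$trajectory), function(k) {
    m <- x$trajectory[[k]]
    tibble::tibble(
      layer = k,
      step = rep(seq_len(nrow(m)), ncol(m)),
      neuron = rep(seq_len(ncol(m)), each = nrow(m)),
      h = as.vector(m)
    )
  }))
}

#' Plot a bifurcation diagram of the scalar cell map
#'
#' Stable branches are drawn as solid points, unstable ones hollow, with a
#' dashed vertical line at the detected critical gain.
#'
#' @param object a [bifurcation_diagram()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  crit <- attr(object, "critical_a")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$a, y = .data$h_star,
                                            shape = .data$stability)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_shape_manual(values = c(stable = 16, unstable = 1,
                                           singular = 8)) +
    ggplot2::labs(x = "feedback gain a", y = "fixed point h*",
                  title = sprintf("Bifurcation diagram (c = %g, u = %g)",
                                  attr(object, "c"), attr(object, "u")))
  if (is.finite(crit)) {
    p <- p + ggplot2::geom_vline(xintercept = crit, linetype = "dashed")
  }
  p
}

#' Plot an IV curve
#'
#' @param object an [iv_curve()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.iv_curve <- function(object, ...) {
  zeros <- attr(object, "zeros")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v, y = .data$current)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = zeros, y = rep(0, length(zeros))) +
    ggplot2::labs(x = "v", y = expression(v - alpha * tanh(v)),
                  title = sprintf("IV curve (alpha = %g): %d zero(s)",
                                  attr(object, "alpha"), length(zeros)))
}

#' Plot training curves of a fit
#'
#' @param object an `rnn_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$split,
                               linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "metric value", title = "Training curves")
}

#' Plot a gate summary: bistable fraction and mean update gate per layer
#'
#' @param object a [summarize_gates()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gate_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("bistable_fraction", "mean_c"),
                              names_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(signal ~ layer, labeller = ggplot2::label_both,
                        scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL,
                  title = "Gate dynamics per layer")
}
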