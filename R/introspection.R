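#' Record gate dynamics of a network on one input sequence
#'
#' Runs a single sequence through a (typically trained) BRC or nBRC network
#' and records the feedback gate `a` and update gate `c` of every neuron at
#' every step. A neuron with `a > 1` is momentarily bistable — it can latch
#' information in its own state — so the recorded gates reveal where and
#' when the network deploys cellular memory.
#'
#' @param model an `rnn_model` with cell `"brc"` or `"nbrc"`.
#' @param x_seq one input sequence: a `T x input_dim` matrix (or a numeric
#'   vector for one-dimensional inputs), e.g. one sample slice
#'   `data$X[i, , ]` of a benchmark dataset.
#' @return a tibble of class `"gate_trace"` with columns `layer`, `step`,
#'   `neuron`, `a`, `c`.
#' @export
#' @examples
#' m <- build_network("nbrc", 1, c(8, 8), 1, "regression-last", seed = 1)
#' tr <- record_gates(m, matrix(rnorm(15), 15, 1))
#' dplyr::count(tr, layer)
record_gates <- function(model, x_seq) {
  stopifnot(inherits(model, "rnn_model"))
  if (!model$cell %in% c("brc", "nbrc")) {
    stop("gate recording requires a BRC or nBRC network", call. = FALSE)
  }
  if (is.vector(x_seq) && !is.matrix(x_seq)) x_seq <- matrix(x_seq, ncol = 1)
  tr <- unroll(model$layers, x_seq, record_gates = TRUE)
  rows <- lapply(seq_along(tr$gates), function(k) {
    a <- tr$gates[[k]]$a; cc <- tr$gates[[k]]$c
    tibble::tibble(
      layer = k,
      step = rep(seq_len(nrow(a)), ncol(a)),
      neuron = rep(seq_len(ncol(a)), each = nrow(a)),
      a = as.vector(a),
      c = as.vector(cc)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, cell = model$cell, class = c("gate_trace", class(out)))
}

#' Summarize gate dynamics per layer and time step
#'
#' Reduces a [record_gates()] trace to the two layer-level signals used to
#' analyse bistable networks: the proportion of bistable neurons
#' (`bistable_fraction`, the fraction with feedback gate strictly above 1 —
#' the regime boundary, so `a = 1` counts as non-bistable) and the mean
#' update-gate value (`mean_c`). A sharp transient dip in `mean_c` makes the
#' layer maximally sensitive to the current input, the signature of the
#' network memorizing a relevant element.
#'
#' @param trace a `"gate_trace"` tibble.
#' @return a tibble of class `"gate_summary"` with columns `layer`, `step`,
#'   `bistable_fraction`, `mean_c`. Plot with [autoplot()].
#' @export
summarize_gates <- function(trace) {
  stopifnot(inherits(trace, "gate_trace") ||
              all(c("layer", "step", "a", "c") %in% names(trace)))
  out <- trace |>
    dplyr::group_by(.data$layer, .data$step) |>
    dplyr::summarise(
      bistable_fraction = mean(.data$a > 1),
      mean_c = mean(.data$c),
      .groups = "drop"
    )
  structure(out, class = c("gate_summary", class(out)))
}

#' Locate the steps with the largest downward update-gate excursions
#'
#' A layer memorizing a relevant input shows a sharp transient *decrease*
#' in its mean update gate — the layer opens itself to the current input.
#' This function returns the `k` steps with the most negative step-to-step
#' drop in the layer's mean `c`. On a trained denoising network these
#' recover the relevant input steps from the gate summary alone.
#'
#' @param summary a [summarize_gates()] tibble.
#' @param layer which layer to analyse.
#' @param k number of dips to return.
#' @return integer vector of `k` step indices, sorted ascending.
#' @export
salient_steps <- function(summary, layer = 1, k = 5) {
  s <- dplyr::filter(summary, .data$layer == !!layer) |>
    dplyr::arrange(.data$step)
  drop <- c(0, diff(s$mean_c))
  sort(s$step[order(drop)[seq_len(k)]])
}

#' Export and re-import a gate summary as CSV
#'
#' @param summary a [summarize_gates()] tibble.
#' @param path CSV file path.
#' @return `export_summary()` returns `path` invisibly; `import_summary()`
#'   returns the summary tibble.
#' @export
export_summary <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_summary
#' @export
import_summary <- function(path) {
  df <- read.csv(path)
  need <- c("layer", "step", "bistable_fraction", "mean_c")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' is not a gate-summary CSV", path), call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  structure(out, class = c("gate_summary", class(out)))
}
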