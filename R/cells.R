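#' Single-step update rules for bistable recurrent cells
#'
#' A bistable recurrent cell (BRC) updates its hidden state as a convex
#' combination of the previous state and a candidate:
#' \deqn{h_t = c_t \odot h_{t-1} + (1 - c_t) \odot \tanh(U x_t + a_t \odot h_{t-1})}
#' with gates
#' \deqn{a_t = 1 + \tanh(U_a x_t + w_a \odot h_{t-1}), \quad
#'       c_t = \sigma(U_c x_t + w_c \odot h_{t-1}).}
#' The feedback gate \eqn{a_t \in (0, 2)} sets the gain on the neuron's own
#' past state inside the candidate nonlinearity: for \eqn{a > 1} the scalar
#' state map becomes bistable and the neuron can latch one of two stable
#' states, a form of cellular memory that never fades. The update gate
#' \eqn{c_t \in (0, 1)} plays the role of a membrane capacitance, setting the
#' convergence speed. All recurrent terms act through Hadamard products, so a
#' BRC neuron's state depends on its own past state only.
#'
#' The recurrently neuromodulated variant (nBRC) keeps the state update
#' elementwise but computes the gates from the whole layer state through full
#' recurrent kernels:
#' \deqn{a_t = 1 + \tanh(U_a x_t + W_a h_{t-1}), \quad
#'       c_t = \sigma(U_c x_t + W_c h_{t-1}).}
#' With diagonal \eqn{W_a}, \eqn{W_c} the nBRC reduces exactly to the BRC.
#'
#' `x` and `h_prev` may be plain vectors (one sequence step) or matrices with
#' one row per batch element; outputs match the input form.
#'
#' @param x input vector (length `input_dim`) or batch matrix
#'   (batch x `input_dim`).
#' @param h_prev previous hidden state, vector (length `hidden`) or batch
#'   matrix (batch x `hidden`).
#' @param w a weight set from [init_weights()] of the matching kind.
#'
#' @return `brc_gates()` / `nbrc_gates()`: a list with elements `a` (feedback
#'   gate, entries in (0, 2)) and `c` (update gate, entries in (0, 1)).
#'   `brc_step()` / `nbrc_step()` / `gru_step()`: the new hidden state, same
#'   shape as `h_prev`.
#' @seealso [unroll()] for running whole sequences through stacked layers.
#' @export
#' @examples
#' w <- init_weights("brc", input_dim = 2, hidden = 3, seed = 7)
#' g <- brc_gates(c(0.3, -1), rep(0, 3), w)
#' stopifnot(all(g$a > 0 & g$a < 2), all(g$c > 0 & g$c < 1))
#' h1 <- brc_step(c(0.3, -1), rep(0, 3), w)
brc_gates <- function(x, h_prev, w) {
  stopifnot(inherits(w, "brc_weights"))
  pa <- gate_preact(x, h_prev, w, w$U_a, w$w_a, w$b_a)
  pc <- gate_preact(x, h_prev, w, w$U_c, w$w_c, w$b_c)
  out_gates(1 + tanh(pa$m), sigmoid(pc$m), pa$vec)
}

#' @rdname brc_gates
#' @export
nbrc_gates <- function(x, h_prev, w) {
  stopifnot(inherits(w, "nbrc_weights"))
  pa <- gate_preact(x, h_prev, w, w$U_a, w$W_a, w$b_a)
  pc <- gate_preact(x, h_prev, w, w$U_c, w$W_c, w$b_c)
  out_gates(1 + tanh(pa$m), sigmoid(pc$m), pa$vec)
}

#' @rdname brc_gates
#' @export
brc_step <- function(x, h_prev, w) {
  stopifnot(inherits(w, "brc_weights"))
  bistable_step(x, h_prev, w, brc_gates(x, h_prev, w))
}

#' @rdname brc_gates
#' @export
nbrc_step <- function(x, h_prev, w) {
  stopifnot(inherits(w, "nbrc_weights"))
  bistable_step(x, h_prev, w, nbrc_gates(x, h_prev, w))
}

#' @rdname brc_gates
#' @export
gru_step <- function(x, h_prev, w) {
  stopifnot(inherits(w, "gru_weights"))
  d <- attr(w, "input_dim"); n <- attr(w, "hidden")
  xb <- as_batch(x, d); hb <- as_batch(h_prev, n, "h_prev")
  z <- sigmoid(affine(xb$m, w$U_z, hb$m, w$W_z, w$b_z))
  r <- sigmoid(affine(xb$m, w$U_r, hb$m, w$W_r, w$b_r))
  cand <- tanh(sweep_bias(xb$m %*% w$U_h + r * (hb$m %*% w$W_h), w$b_h))
  h <- z * hb$m + (1 - z) * cand
  if (xb$vec) drop(h) else h
}

# shared helpers ------------------------------------------------------------

sigmoid <- function(x) plogis(x)

sweep_bias <- function(m, b) if (is.null(b)) m else sweep(m, 2L, b, "+")

affine <- function(xm, U, hm, W, b) sweep_bias(xm %*% U + hm %*% W, b)

# Gate pre-activation; `rec` is either a per-neuron gain vector (BRC) or a
# full hidden-by-hidden kernel (nBRC).
gate_preact <- function(x, h_prev, w, U, rec, b) {
  d <- attr(w, "input_dim"); n <- attr(w, "hidden")
  xb <- as_batch(x, d); hb <- as_batch(h_prev, n, "h_prev")
  recur <- if (is.matrix(rec)) hb$m %*% rec else hb$m * rep(rec, each = nrow(hb$m))
  list(m = sweep_bias(xb$m %*% U + recur, b), vec = xb$vec && hb$vec)
}

out_gates <- function(a, c, vec) {
  if (vec) list(a = drop(a), c = drop(c)) else list(a = a, c = c)
}

# h-update shared by BRC and nBRC: elementwise in h_prev by construction.
bistable_step <- function(x, h_prev, w, gates) {
  d <- attr(w, "input_dim"); n <- attr(w, "hidden")
  xb <- as_batch(x, d); hb <- as_batch(h_prev, n, "h_prev")
  a <- if (is.matrix(gates$a)) gates$a else matrix(gates$a, nrow(hb$m), n, byrow = nrow(hb$m) > 1)
  cc <- if (is.matrix(gates$c)) gates$c else matrix(gates$c, nrow(hb$m), n, byrow = nrow(hb$m) > 1)
  cand <- tanh(sweep_bias(xb$m %*% w$U + a * hb$m, w$b))
  h <- cc * hb$m + (1 - cc) * cand
  if (xb$vec && hb$vec) drop(h) else h
}

#' Unroll stacked recurrent layers over an input sequence
#'
#' Runs a sequence through a stack of recurrent layers (all of the same cell
#' kind), layer k receiving the hidden state of layer k - 1 as its input at
#' each step. The initial state of every layer is the zero vector (a fixed
#' constant, not trainable).
#'
#' @param layers a list of weight sets from [init_weights()], all of the same
#'   cell kind; layer k's `input_dim` must equal layer k - 1's `hidden`.
#' @param inputs a sequence as a `T x input_dim` matrix (or a numeric vector
#'   for one-dimensional inputs), one row per time step.
#' @param record_gates logical; record the feedback and update gate values of
#'   every BRC/nBRC neuron at every step? (Ignored for GRU layers.)
#'
#' @return a list with class `"rnn_trace"`:
#'   \describe{
#'     \item{final}{list of final hidden-state vectors, one per layer.}
#'     \item{trajectory}{list of `T x hidden` state matrices, one per layer.}
#'     \item{gates}{when `record_gates = TRUE`, a list per layer with `T x
#'       hidden` matrices `a` and `c`; otherwise `NULL`.}
#'     \item{cell}{the cell kind.}
#'   }
#' @export
#' @examples
#' layers <- list(
#'   init_weights("nbrc", 1, 8, seed = 1),
#'   init_weights("nbrc", 8, 8, seed = 2)
#' )
#' tr <- unroll(layers, matrix(rnorm(20), 20, 1), record_gates = TRUE)
#' dim(tr$trajectory[[2]])
unroll <- function(layers, inputs, record_gates = FALSE) {
  stopifnot(is.list(layers), length(layers) >= 1)
  cells <- vapply(layers, cell_kind, character(1))
  if (length(unique(cells)) != 1L) {
    stop("all layers must share one cell kind", call. = FALSE)
  }
  cell <- cells[1]
  if (is.vector(inputs) && !is.matrix(inputs)) inputs <- matrix(inputs, ncol = 1)
  n_steps <- nrow(inputs)
  if (is.null(n_steps) || n_steps < 1) stop("empty input sequence", call. = FALSE)
  for (k in seq_along(layers)) {
    want <- attr(layers[[k]], "input_dim")
    have <- if (k == 1L) ncol(inputs) else attr(layers[[k - 1L]], "hidden")
    if (want != have) {
      stop(sprintf("layer %d expects input_dim %d but receives %d", k, want, have),
        call. = FALSE)
    }
  }
  step_fun <- switch(cell, brc = brc_step, nbrc = nbrc_step, gru = gru_step)
  gate_fun <- switch(cell, brc = brc_gates, nbrc = nbrc_gates, NULL)
  record_gates <- record_gates && !is.null(gate_fun)

  traj <- lapply(layers, function(w) matrix(NA_real_, n_steps, attr(w, "hidden")))
  gates <- if (record_gates) {
    lapply(layers, function(w) list(
      a = matrix(NA_real_, n_steps, attr(w, "hidden")),
      c = matrix(NA_real_, n_steps, attr(w, "hidden"))
    ))
  }
  h <- lapply(layers, function(w) numeric(attr(w, "hidden")))
  for (t in seq_len(n_steps)) {
    x <- inputs[t, ]
    for (k in seq_along(layers)) {
      if (record_gates) {
        g <- gate_fun(x, h[[k]], layers[[k]])
        gates[[k]]$a[t, ] <- g$a
        gates[[k]]$c[t, ] <- g$c
      }
      h[[k]] <- step_fun(x, h[[k]], layers[[k]])
      traj[[k]][t, ] <- h[[k]]
      x <- h[[k]]
    }
  }
  structure(
    list(final = h, trajectory = traj, gates = gates, cell = cell),
    class = "rnn_trace"
  )
}

#' @export
print.rnn_trace <- function(x, ...) {
  cat(sprintf(
    "<rnn_trace> %s, %d layer(s), %d steps, gates %srecorded\n",
    x$cell, length(x$trajectory), nrow(x$trajectory[[1]]),
    if (is.null(x$gates)) "not " else ""
  ))
  invisible(x)
}
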