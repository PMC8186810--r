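#' Initialize the trainable weights of a recurrent layer
#'
#' Creates a weight set for one layer of bistable recurrent cells (`"brc"`),
#' recurrently neuromodulated bistable recurrent cells (`"nbrc"`), or gated
#' recurrent units (`"gru"`).
#'
#' Input-to-hidden kernels (`U`, `U_a`, `U_c`, and the GRU equivalents) use
#' Glorot-uniform variance scaling. Full recurrent kernels (`W_a`, `W_c` for the
#' nBRC; `W_z`, `W_r`, `W_h` for the GRU) are initialized orthogonally, the
#' standard choice for recurrent matrices. The BRC per-neuron recurrent gains
#' `w_a`, `w_c` are drawn from a small uniform distribution, so every neuron
#' starts close to the gate midpoint (feedback gate near 1, update gate near
#' 1/2). Additive biases are initialized to zero so that at initialization the
#' cell computes exactly the bias-free update equations; set `bias = FALSE` to
#' drop the bias terms altogether.
#'
#' @param cell one of `"brc"`, `"nbrc"`, `"gru"`.
#' @param input_dim integer, dimension of the input vector fed to the layer.
#' @param hidden integer, number of neurons in the layer.
#' @param seed optional integer seed; when given, initialization is
#'   reproducible and the caller's RNG state is left untouched.
#' @param bias logical; include additive bias vectors (initialized to zero)?
#'
#' @return a list of named weight arrays with class `"brc_weights"`,
#'   `"nbrc_weights"` or `"gru_weights"` (all inheriting from
#'   `"rnn_weights"`), carrying `input_dim` and `hidden` attributes.
#' @export
#' @examples
#' w <- init_weights("brc", input_dim = 1, hidden = 4, seed = 1)
#' str(w, give.attr = FALSE)
init_weights <- function(cell = c("brc", "nbrc", "gru"),
                         input_dim, hidden, seed = NULL, bias = TRUE) {
  cell <- match.arg(cell)
  stopifnot(input_dim >= 1, hidden >= 1)
  draw <- function() {
    glorot <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(runif(nin * nout, -lim, lim), nin, nout)
    }
    orthogonal <- function(n) {
      m <- matrix(rnorm(n * n), n, n)
      qr.Q(qr(m))
    }
    zeros <- function(n) numeric(n)
    w <- switch(cell,
      brc = list(
        U   = glorot(input_dim, hidden),
        U_a = glorot(input_dim, hidden),
        U_c = glorot(input_dim, hidden),
        w_a = runif(hidden, -0.1, 0.1),
        w_c = runif(hidden, -0.1, 0.1)
      ),
      nbrc = list(
        U   = glorot(input_dim, hidden),
        U_a = glorot(input_dim, hidden),
        U_c = glorot(input_dim, hidden),
        W_a = orthogonal(hidden),
        W_c = orthogonal(hidden)
      ),
      gru = list(
        U_z = glorot(input_dim, hidden),
        U_r = glorot(input_dim, hidden),
        U_h = glorot(input_dim, hidden),
        W_z = orthogonal(hidden),
        W_r = orthogonal(hidden),
        W_h = orthogonal(hidden)
      )
    )
    if (bias) {
      w <- c(w, switch(cell,
        gru = list(b_z = zeros(hidden), b_r = zeros(hidden), b_h = zeros(hidden)),
        list(b_a = zeros(hidden), b_c = zeros(hidden), b = zeros(hidden))
      ))
    }
    w
  }
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(w,
    input_dim = input_dim, hidden = hidden, bias = bias,
    class = c(paste0(cell, "_weights"), "rnn_weights")
  )
}

#' @export
print.rnn_weights <- function(x, ...) {
  cat(sprintf(
    "<%s> input_dim = %d, hidden = %d, parameters = %d\n",
    class(x)[1], attr(x, "input_dim"), attr(x, "hidden"), n_params(x)
  ))
  invisible(x)
}

cell_kind <- function(w) sub("_weights$", "", class(w)[1])

#' Number of trainable parameters in a weight set or model
#'
#' @param x an `rnn_weights` object or an `rnn_model`.
#' @return integer count of scalar parameters.
#' @export
n_params <- function(x) UseMethod("n_params")

#' @export
n_params.rnn_weights <- function(x) sum(vapply(x, length, integer(1)))

check_weights <- function(w, input_dim = NULL) {
  stopifnot(inherits(w, "rnn_weights"))
  if (!all(vapply(w, function(a) all(is.finite(a)), logical(1)))) {
    stop("weight arrays contain non-finite entries", call. = FALSE)
  }
  if (!is.null(input_dim) && attr(w, "input_dim") != input_dim) {
    stop(sprintf(
      "input dimension mismatch: weights expect %d, got %d",
      attr(w, "input_dim"), input_dim
    ), call. = FALSE)
  }
  invisible(w)
}

# Coerce x (vector of length d, or batch-by-d matrix) to a matrix; remember
# whether the caller passed a plain vector so results can be returned in kind.
as_batch <- function(x, d, what = "input") {
  if (is.matrix(x)) {
    if (ncol(x) != d) {
      stop(sprintf("%s has %d columns, expected %d", what, ncol(x), d),
        call. = FALSE)
    }
    list(m = x, vec = FALSE)
  } else {
    if (length(x) != d) {
      stop(sprintf("%s has length %d, expected %d", what, length(x), d),
        call. = FALSE)
    }
    list(m = matrix(x, 1L, d), vec = TRUE)
  }
}
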