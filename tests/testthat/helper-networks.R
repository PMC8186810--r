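# Shared helpers for building small, fully controlled cells and networks.

# Weights with every array set to zero (gates sit at a = 1, c = 0.5).
zero_weights <- function(cell, input_dim, hidden) {
  w <- init_weights(cell, input_dim, hidden, seed = 1)
  for (nm in names(w)) w[[nm]] <- w[[nm]] * 0
  w
}

# A single-neuron BRC whose gates are frozen at constants: a = 1 + tanh(pa0),
# c = sigmoid(pc0), achieved through the bias terms with zero kernels.
frozen_brc <- function(a, c) {
  stopifnot(a > 0, a < 2, c > 0, c < 1)
  w <- zero_weights("brc", 1, 1)
  w$b_a <- atanh(a - 1)
  w$b_c <- log(c / (1 - c))
  w
}

# Central finite-difference gradient of f at flat parameter list `flat`.
fd_gradient <- function(f, flat, eps = 1e-6) {
  g <- lapply(flat, function(a) a * 0)
  for (nm in names(flat)) {
    for (j in seq_along(flat[[nm]])) {
      up <- flat; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- flat; dn[[nm]][j] <- dn[[nm]][j] - eps
      g[[nm]][j] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  g
}

# Loss of a model under flat parameters on a fixed batch.
flat_loss_fn <- function(model, xs, y, out_step = NULL) {
  function(flat) {
    m <- bistablernn:::set_flat(model, flat)
    fw <- bistablernn:::net_forward(m, xs)
    bistablernn:::readout_loss(m, fw, y, out_step)$loss
  }
}

max_rel_err <- function(a, b) {
  num <- abs(unlist(a) - unlist(b))
  den <- pmax(abs(unlist(a)) + abs(unlist(b)), 1e-8)
  max(num / den)
}
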