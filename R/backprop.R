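# Network-level forward/backward passes over time-stacked batches.
#
# A batch of sequences is held TIME-STACKED: one (T*B) x d matrix whose row
# block ((t-1)*B + 1):(t*B) is the batch input at step t. The per-layer hot
# loops live in src/cells.cpp (RcppArmadillo); this file dispatches per cell
# kind and maps gradient arrays back onto the named weight fields. Gradients
# are exact analytic backpropagation through time; the test suite checks
# them against central finite differences, and the compiled forward pass is
# cross-checked against the plain-R step functions in cells.R.

step_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Stack a list of per-step B x d matrices into the (T*B) x d layout.
stack_steps <- function(xs) do.call(rbind, xs)

empty_mat <- matrix(0, 0, 0)

layer_forward <- function(w, Xs, Tn, B, keep) {
  cell <- cell_kind(w)
  has_bias <- isTRUE(attr(w, "bias"))
  if (cell == "gru") {
    gru_forward_cpp(Xs, w$U_z, w$U_r, w$U_h, w$W_z, w$W_r, w$W_h,
                    w$b_z %||% numeric(0), w$b_r %||% numeric(0),
                    w$b_h %||% numeric(0), has_bias, Tn, B, keep)
  } else {
    diag_rec <- cell == "brc"
    bi_forward_cpp(Xs, w$U, w$U_a, w$U_c,
                   w$W_a %||% empty_mat, w$W_c %||% empty_mat,
                   w$w_a %||% numeric(0), w$w_c %||% numeric(0),
                   w$b %||% numeric(0), w$b_a %||% numeric(0),
                   w$b_c %||% numeric(0), diag_rec, has_bias, Tn, B, keep)
  }
}

layer_backward <- function(w, cache, Dinj, Tn, B) {
  cell <- cell_kind(w)
  has_bias <- isTRUE(attr(w, "bias"))
  if (cell == "gru") {
    r <- gru_backward_cpp(cache$Xs, w$U_z, w$U_r, w$U_h, w$W_z, w$W_r, w$W_h,
                          cache$Z, cache$R, cache$WH, cache$CAND, cache$HPREV,
                          Dinj, has_bias, Tn, B)
    g <- list(U_z = r$gUz, U_r = r$gUr, U_h = r$gUh,
              W_z = r$gWz, W_r = r$gWr, W_h = r$gWh)
    if (has_bias) {
      g$b_z <- drop(r$gbz); g$b_r <- drop(r$gbr); g$b_h <- drop(r$gbh)
    }
  } else {
    diag_rec <- cell == "brc"
    r <- bi_backward_cpp(cache$Xs, w$U, w$U_a, w$U_c,
                         w$W_a %||% empty_mat, w$W_c %||% empty_mat,
                         w$w_a %||% numeric(0), w$w_c %||% numeric(0),
                         cache$TA, cache$CC, cache$CAND, cache$HPREV,
                         Dinj, diag_rec, has_bias, Tn, B)
    g <- list(U = r$gU, U_a = r$gUa, U_c = r$gUc)
    if (diag_rec) {
      g$w_a <- drop(r$gwa); g$w_c <- drop(r$gwc)
    } else {
      g$W_a <- r$gWa; g$W_c <- r$gWc
    }
    if (has_bias) {
      g$b_a <- drop(r$gba); g$b_c <- drop(r$gbc); g$b <- drop(r$gb)
    }
  }
  list(Dx = r$Dx, grads = g[names(w)])
}

# Forward over a time-stacked batch. Returns the stacked top-layer states
# (H_top row block t = states after step t) plus per-layer caches.
net_forward_stacked <- function(model, Xs, Tn, B, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers))
  H <- Xs
  finals <- vector("list", length(model$layers))
  for (k in seq_along(model$layers)) {
    st <- layer_forward(model$layers[[k]], H, Tn, B, keep_caches)
    if (keep_caches) {
      st$Xs <- H
      caches[[k]] <- st
    }
    H <- st$H
    finals[[k]] <- drop(st$h_final)
  }
  list(H_top = H, final = finals, caches = caches, Tn = Tn, B = B)
}

# Compatibility wrapper taking a list of per-step B x d matrices.
net_forward <- function(model, xs, keep_caches = FALSE) {
  B <- nrow(xs[[1]])
  fw <- net_forward_stacked(model, stack_steps(xs), length(xs), B, keep_caches)
  fw$top <- lapply(seq_len(fw$Tn), function(t) {
    fw$H_top[step_rows(t, fw$B), , drop = FALSE]
  })
  fw
}

# Backward pass. `Dinj` is the (T*B) x n_top matrix of dL/dh for the top
# layer (zeros where the loss does not look at the state).
net_backward_stacked <- function(model, caches, Dinj, Tn, B) {
  L <- length(model$layers)
  grads <- vector("list", L)
  D <- Dinj
  for (k in rev(seq_len(L))) {
    res <- layer_backward(model$layers[[k]], caches[[k]], D, Tn, B)
    grads[[k]] <- res$grads
    D <- res$Dx
  }
  grads
}
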