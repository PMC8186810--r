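#' Build a stacked recurrent network with an affine readout
#'
#' Stacks recurrent layers of one cell kind and attaches a single affine
#' readout applied to the top layer's hidden state at the prediction step(s).
#' The readout is deliberately minimal: the network is asked for its output
#' only after (or while) receiving the last relevant elements of the
#' sequence, so the loss is computed at those steps alone.
#'
#' @param cell `"brc"`, `"nbrc"` or `"gru"`.
#' @param input_dim dimension of each sequence element.
#' @param hidden integer vector of layer widths, e.g. `c(128, 128)`.
#' @param output_dim readout dimension (1 for scalar regression, number of
#'   classes for classification).
#' @param task one of `"regression-last"` (scalar target, read out at the
#'   final step), `"regression-last5"` (five scalar targets read out at the
#'   five final steps), `"classification"` (softmax read out at the final
#'   step, or at a per-sample step when the dataset provides one).
#' @param seed optional integer seed for reproducible initialization.
#' @param bias include additive biases in the cells?
#'
#' @return an object of class `"rnn_model"`.
#' @export
#' @examples
#' m <- build_network("nbrc", 1, c(16, 16), 1, "regression-last", seed = 1)
#' m
build_network <- function(cell = c("brc", "nbrc", "gru"),
                          input_dim, hidden, output_dim = 1L,
                          task = c("regression-last", "regression-last5",
                                   "classification"),
                          seed = NULL, bias = TRUE) {
  cell <- match.arg(cell)
  task <- match.arg(task)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), output_dim >= 1)
  seeds <- derive_seeds(seed, length(hidden) + 1L)
  dims <- c(input_dim, hidden)
  layers <- lapply(seq_along(hidden), function(k) {
    init_weights(cell, dims[k], dims[k + 1L], seed = seeds[k], bias = bias)
  })
  n_top <- hidden[length(hidden)]
  draw_read <- function() {
    # scaled-down variance init: an untrained network then predicts near 0,
    # so its copy-task MSE sits at the chance level 1
    lim <- 0.1 * sqrt(6 / (n_top + output_dim))
    list(
      V = matrix(runif(n_top * output_dim, -lim, lim), n_top, output_dim),
      b = numeric(output_dim)
    )
  }
  readout <- if (is.null(seed)) draw_read() else {
    withr::with_seed(seeds[length(seeds)], draw_read())
  }
  structure(
    list(cell = cell, layers = layers, readout = readout,
         task = task, input_dim = input_dim, hidden = hidden,
         output_dim = output_dim),
    class = "rnn_model"
  )
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf(
    "<rnn_model> %s, layers [%s], readout %d, task %s, %d parameters\n",
    x$cell, paste(x$hidden, collapse = ", "), x$output_dim, x$task, n_params(x)
  ))
  invisible(x)
}

#' @export
n_params.rnn_model <- function(x) {
  sum(vapply(x$layers, n_params, integer(1))) +
    length(x$readout$V) + length(x$readout$b)
}

# Deterministic sub-seed derivation so one user seed drives all RNG streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  (as.integer(seed) %% 1000003L) * 1009L + 7L * seq_len(n)
}

# --- batching helpers ------------------------------------------------------

# Slice samples `idx` of an n x T x d array into the time-stacked
# (T*B) x d layout used by the forward/backward engine (row block t holds
# the batch inputs at step t); column-major flattening does this directly.
stack_batch <- function(X, idx) {
  Tn <- dim(X)[2]; d <- dim(X)[3]; B <- length(idx)
  list(Xs = matrix(X[idx, , , drop = FALSE], B * Tn, d), Tn = Tn, B = B)
}

# Time-major list view, used by tests and small-scale paths.
slice_batch <- function(X, idx) {
  Tn <- dim(X)[2]; d <- dim(X)[3]
  lapply(seq_len(Tn), function(t) matrix(X[idx, t, ], length(idx), d))
}

as_target_matrix <- function(y, idx = NULL) {
  m <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

one_hot <- function(labels, k) {
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Readout + loss at the task's prediction steps. `fw` is the result of
# net_forward_stacked(); returns the loss, the readout gradient, and the
# time-stacked dL/dh injection matrix for the top layer.
readout_loss <- function(model, fw, y, out_step = NULL) {
  V <- model$readout$V; b <- model$readout$b
  Tn <- fw$Tn; B <- fw$B
  n_top <- ncol(fw$H_top)
  top_at <- function(t) fw$H_top[step_rows(t, B), , drop = FALSE]
  Dinj <- matrix(0, Tn * B, n_top)
  gV <- array(0, dim(V)); gb <- numeric(length(b))
  if (model$task == "regression-last") {
    top <- top_at(Tn)
    pred <- sweep_bias(top %*% V, b)
    resid <- pred - y
    loss <- mean(resid^2)
    dp <- 2 * resid / length(resid)
    gV <- crossprod(top, dp); gb <- colSums(dp)
    Dinj[step_rows(Tn, B), ] <- tcrossprod(dp, V)
  } else if (model$task == "regression-last5") {
    if (Tn < 5L) stop("sequence shorter than the five output steps", call. = FALSE)
    steps <- (Tn - 4L):Tn
    loss <- 0
    for (i in seq_along(steps)) {
      top <- top_at(steps[i])
      pred <- sweep_bias(top %*% V, b)
      resid <- pred - y[, i, drop = FALSE]
      loss <- loss + sum(resid^2)
      dp <- 2 * resid / (B * 5)
      gV <- gV + crossprod(top, dp); gb <- gb + colSums(dp)
      Dinj[step_rows(steps[i], B), ] <- tcrossprod(dp, V)
    }
    loss <- loss / (B * 5)
  } else { # classification
    if (is.null(out_step)) out_step <- rep(Tn, B)
    sel_rows <- (out_step - 1L) * B + seq_len(B) # row of sample b at its step
    sel <- fw$H_top[sel_rows, , drop = FALSE]
    logits <- sweep_bias(sel %*% V, b)
    p <- softmax_rows(logits)
    labels <- as.integer(y)
    loss <- -mean(log(pmax(p[cbind(seq_len(B), labels)], 1e-12)))
    dl <- (p - one_hot(labels, model$output_dim)) / B
    gV <- crossprod(sel, dl); gb <- colSums(dl)
    Dinj[sel_rows, ] <- tcrossprod(dl, V)
  }
  list(loss = loss, gV = gV, gb = gb, Dinj = Dinj)
}

# One full forward + backward over a time-stacked batch.
net_loss_grads_stacked <- function(model, Xs, Tn, B, y, out_step = NULL) {
  fw <- net_forward_stacked(model, Xs, Tn, B, keep_caches = TRUE)
  rl <- readout_loss(model, fw, y, out_step)
  layer_grads <- net_backward_stacked(model, fw$caches, rl$Dinj, Tn, B)
  list(loss = rl$loss, layer_grads = layer_grads,
       readout_grads = list(V = rl$gV, b = rl$gb))
}

# Compatibility wrapper over a time-major list of step matrices.
net_loss_grads <- function(model, xs, y, out_step = NULL) {
  net_loss_grads_stacked(model, stack_steps(xs), length(xs), nrow(xs[[1]]),
                         y, out_step)
}

# --- flat parameter view for the optimizer ---------------------------------

get_flat <- function(model) {
  out <- list()
  for (k in seq_along(model$layers)) {
    w <- model$layers[[k]]
    for (nm in names(w)) out[[paste0("L", k, ".", nm)]] <- w[[nm]]
  }
  out$`readout.V` <- model$readout$V
  out$`readout.b` <- model$readout$b
  out
}

set_flat <- function(model, flat) {
  for (k in seq_along(model$layers)) {
    for (nm in names(model$layers[[k]])) {
      model$layers[[k]][[nm]] <- flat[[paste0("L", k, ".", nm)]]
    }
  }
  model$readout$V <- flat$`readout.V`
  model$readout$b <- flat$`readout.b`
  model
}

flat_grads <- function(model, gr) {
  out <- list()
  for (k in seq_along(gr$layer_grads)) {
    for (nm in names(gr$layer_grads[[k]])) {
      out[[paste0("L", k, ".", nm)]] <- gr$layer_grads[[k]][[nm]]
    }
  }
  out$`readout.V` <- gr$readout_grads$V
  out$`readout.b` <- gr$readout_grads$b
  out
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(a) a * 0), v = lapply(flat, function(a) a * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

# --- training --------------------------------------------------------------

#' Train a recurrent network with ADAM
#'
#' Minimizes the task loss by backpropagation through time with the ADAM
#' optimizer (learning rate 1e-3, mini-batches of 100 by default). No
#' gradient clipping, learning-rate schedule or weight decay is applied
#' unless requested. A non-finite loss aborts the run and flags the fit as
#' diverged.
#'
#' @param model an [build_network()] model.
#' @param train_data,test_data benchmark datasets (see [gen_copy()],
#'   [gen_denoise()]); `test_data` may be `NULL`.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param lr ADAM learning rate.
#' @param seed integer seed driving shuffling (and nothing else).
#' @param eval_every evaluate on `test_data` every this many epochs
#'   (`0` = only after the final epoch).
#' @param clip optional global-norm gradient clip; `NULL` (default) disables.
#' @param verbose print a line per epoch?
#'
#' @return an object of class `"rnn_fit"`: the trained `model`, a `history`
#'   tibble of per-epoch metrics (both train loss and test MSE are logged so
#'   learning curves can be drawn from either), final `metrics`, and a
#'   `diverged` flag. Supports [tidy()], [glance()] and [autoplot()].
#' @export
train_network <- function(model, train_data, test_data = NULL, epochs = 50,
                          batch_size = 100, lr = 1e-3, seed = 0,
                          eval_every = 1, clip = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "rnn_model"))
  check_dataset_task(model, train_data)
  n <- dim(train_data$X)[1]
  flat <- get_flat(model)
  state <- adam_init(flat)
  history <- list()
  diverged <- FALSE
  shuffle_seeds <- withr::with_seed(derive_seeds(seed, 1L)[1],
                                    sample.int(.Machine$integer.max, epochs))
  for (ep in seq_len(epochs)) {
    idx_all <- withr::with_seed(shuffle_seeds[ep], sample.int(n))
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0; nb <- 0L
    for (s in starts) {
      idx <- idx_all[s:min(s + batch_size - 1L, n)]
      sb <- stack_batch(train_data$X, idx)
      y <- batch_targets(model, train_data, idx)
      gr <- net_loss_grads_stacked(model, sb$Xs, sb$Tn, sb$B,
                                   y$targets, y$out_step)
      if (!is.finite(gr$loss)) {
        diverged <- TRUE
        warning(sprintf("training diverged at epoch %d (non-finite loss); run aborted",
                        ep), call. = FALSE)
        break
      }
      g <- flat_grads(model, gr)
      if (!is.null(clip)) g <- clip_global_norm(g, clip)
      upd <- adam_step(flat, g, state, lr = lr)
      flat <- upd$flat; state <- upd$state
      model <- set_flat(model, flat)
      ep_loss <- ep_loss + gr$loss; nb <- nb + 1L
    }
    if (diverged) break
    history[[length(history) + 1L]] <-
      tibble::tibble(epoch = ep, split = "train", metric = "loss",
                     value = ep_loss / nb)
    do_eval <- !is.null(test_data) && eval_every > 0 && (ep %% eval_every == 0)
    if (do_eval) {
      tm <- eval_metrics(model, test_data)
      history[[length(history) + 1L]] <-
        tibble::tibble(epoch = ep, split = "test", metric = names(tm),
                       value = unname(tm))
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  train loss %.5f", ep, epochs, ep_loss / nb))
    }
  }
  metrics <- if (!is.null(test_data) && !diverged) {
    eval_metrics(model, test_data)
  } else {
    c(train_loss = if (length(history)) utils::tail(dplyr::filter(
      dplyr::bind_rows(history), .data$split == "train")$value, 1) else NA_real_)
  }
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         metrics = metrics, diverged = diverged,
         config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                       seed = seed, clip = clip)),
    class = "rnn_fit"
  )
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat(sprintf("<rnn_fit> %s [%s]%s\n", x$model$cell,
              paste(x$model$hidden, collapse = ", "),
              if (x$diverged) " (DIVERGED)" else ""))
  if (length(x$metrics)) {
    cat("  ", paste(sprintf("%s = %.5f", names(x$metrics), x$metrics),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

check_dataset_task <- function(model, data) {
  need <- switch(data$task %||% model$task,
    copy = "regression-last", denoise = "regression-last5",
    classification = "classification", model$task)
  if (model$task != need) {
    stop(sprintf("dataset task '%s' does not match model task '%s'",
                 data$task, model$task), call. = FALSE)
  }
  if (dim(data$X)[3] != model$input_dim) {
    stop("dataset input dimension does not match the model", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

batch_targets <- function(model, data, idx) {
  if (model$task == "classification") {
    list(targets = data$y[idx], out_step = data$out_step[idx] %||% NULL)
  } else {
    list(targets = as_target_matrix(data$y, idx), out_step = NULL)
  }
}

# --- evaluation ------------------------------------------------------------

predict_steps <- function(model, data, idx) {
  sb <- stack_batch(data$X, idx)
  fw <- net_forward_stacked(model, sb$Xs, sb$Tn, sb$B)
  Tn <- sb$Tn; B <- sb$B
  top_at <- function(t) fw$H_top[step_rows(t, B), , drop = FALSE]
  V <- model$readout$V; b <- model$readout$b
  if (model$task == "regression-last") {
    sweep_bias(top_at(Tn) %*% V, b)
  } else if (model$task == "regression-last5") {
    do.call(cbind, lapply((Tn - 4L):Tn, function(t) {
      sweep_bias(top_at(t) %*% V, b)
    }))
  } else {
    out_step <- data$out_step[idx] %||% rep(Tn, B)
    sel <- fw$H_top[(out_step - 1L) * B + seq_len(B), , drop = FALSE]
    sweep_bias(sel %*% V, b)
  }
}

#' Predictions of a trained network on a benchmark dataset
#'
#' @param object an `rnn_model` (or the `model` element of an `rnn_fit`).
#' @param data a benchmark dataset.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return a matrix of predictions: one row per sample (columns are the five
#'   output steps for the denoising task, class logits for classification).
#' @export
predict.rnn_model <- function(object, data, batch_size = 500, ...) {
  n <- dim(data$X)[1]
  starts <- seq(1L, n, by = batch_size)
  do.call(rbind, lapply(starts, function(s) {
    predict_steps(object, data, s:min(s + batch_size - 1L, n))
  }))
}

#' Evaluate a regression network: mean squared error on a test set
#'
#' For the copy task this is the MSE of the final-step prediction against the
#' first input; for the denoising task the squared errors of the five
#' final-step outputs against the five stored values, averaged over the five
#' outputs and over samples (see [denoise_loss()]).
#'
#' @inheritParams predict.rnn_model
#' @param model an `rnn_model`.
#' @return scalar MSE.
#' @export
evaluate_regression <- function(model, data, batch_size = 500) {
  pred <- predict.rnn_model(model, data, batch_size)
  y <- as_target_matrix(data$y)
  mean((pred - y)^2)
}

#' Evaluate a classification network: accuracy and macro-averaged F1
#'
#' Macro F1 is the unweighted mean over classes of per-class F1; a class with
#' no true and no predicted samples contributes 0.
#'
#' @inheritParams evaluate_regression
#' @return named numeric vector `c(accuracy = , macro_f1 = )`.
#' @export
evaluate_classification <- function(model, data, batch_size = 500) {
  logits <- predict.rnn_model(model, data, batch_size)
  pred <- max.col(logits, ties.method = "first")
  truth <- as.integer(data$y)
  c(accuracy = mean(pred == truth),
    macro_f1 = macro_f1(pred, truth, model$output_dim))
}

#' Macro-averaged F1 score
#'
#' @param pred,truth integer class labels in `1:n_classes`.
#' @param n_classes number of classes to average over.
#' @return scalar in `[0, 1]`.
#' @export
macro_f1 <- function(pred, truth, n_classes = max(c(pred, truth))) {
  f1 <- vapply(seq_len(n_classes), function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

eval_metrics <- function(model, data) {
  if (model$task == "classification") {
    evaluate_classification(model, data)
  } else {
    c(mse = evaluate_regression(model, data))
  }
}

#' Run the multi-seed training protocol for one cell on one benchmark
#'
#' Trains one network per seed under identical data and reports per-seed and
#' aggregate test metrics (mean and standard deviation across seeds), the
#' form in which benchmark results are conventionally reported.
#'
#' @param cell,hidden passed to [build_network()].
#' @param train_data,test_data benchmark datasets.
#' @param seeds integer vector; one network is initialized and trained per
#'   seed.
#' @inheritParams train_network
#' @param ... passed on to [train_network()].
#' @return an object of class `"protocol_result"`: a list with `per_seed`
#'   (tibble of final metrics per seed), `summary` (mean/sd per metric),
#'   `fits` (list of `rnn_fit`s) and the configuration. `tidy()` returns the
#'   per-seed table, `glance()` the aggregate row.
#' @export
train_protocol <- function(cell, hidden, train_data, test_data,
                           seeds = c(0, 1, 2), epochs = 50, batch_size = 100,
                           lr = 1e-3, ...) {
  output_dim <- if (train_data$task == "classification") {
    length(unique(as.integer(train_data$y)))
  } else 1L
  task <- switch(train_data$task,
    copy = "regression-last", denoise = "regression-last5",
    classification = "classification",
    stop("unknown dataset task", call. = FALSE))
  fits <- lapply(seeds, function(s) {
    model <- build_network(cell, dim(train_data$X)[3], hidden, output_dim,
                           task, seed = s)
    train_network(model, train_data, test_data, epochs = epochs,
                  batch_size = batch_size, lr = lr, seed = s, ...)
  })
  per_seed <- dplyr::bind_rows(lapply(seq_along(seeds), function(i) {
    tibble::tibble(seed = seeds[i], metric = names(fits[[i]]$metrics),
                   value = unname(fits[[i]]$metrics),
                   diverged = fits[[i]]$diverged)
  }))
  summary <- per_seed |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop")
  structure(
    list(per_seed = per_seed, summary = summary, fits = fits,
         config = list(cell = cell, hidden = hidden, seeds = seeds,
                       epochs = epochs, batch_size = batch_size, lr = lr)),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s [%s], %d seed(s)\n", x$config$cell,
              paste(x$config$hidden, collapse = ", "),
              length(x$config$seeds)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s = %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
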