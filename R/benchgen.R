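#' Generate the copy-first-input benchmark
#'
#' Each sample is a one-dimensional time series \eqn{x_0, \dots, x_T} of
#' i.i.d. standard-normal values; after receiving \eqn{x_T} the network must
#' output \eqn{x_0}. All later entries are pure noise the network must learn
#' to ignore, so the task isolates long-term memory: the best input-agnostic
#' predictor (the constant 0) attains an expected MSE of exactly 1, the
#' variance of \eqn{x_0} — chance level for this benchmark.
#'
#' Steps are indexed 0 to `T` (sequence length `T + 1`), the only indexing
#' for which "after receiving \eqn{x_T}" is well defined alongside "`T`
#' time-steps".
#'
#' @param T number of time steps after the initial one (sequence length is
#'   `T + 1`).
#' @param n number of samples.
#' @param seed integer seed; generation is a pure function of `(T, n, seed)`.
#' @return a benchmark dataset of class `"benchmark_data"`: a list with `X`
#'   (`n x (T+1) x 1` array), `y` (length-`n` targets, `= X[, 1, 1]`),
#'   `task = "copy"` and `meta`.
#' @export
#' @examples
#' d <- gen_copy(T = 5, n = 3, seed = 1)
#' stopifnot(identical(d$y, d$X[, 1, 1]))
gen_copy <- function(T, n, seed = 0) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  stopifnot(n >= 1)
  X <- withr::with_seed(seed, array(rnorm(n * (T + 1)), dim = c(n, T + 1, 1)))
  structure(
    list(X = X, y = X[, 1, 1], task = "copy",
         meta = list(T = T, n = n, seed = seed)),
    class = "benchmark_data"
  )
}

#' Generate the denoising benchmark
#'
#' Each sample is a two-dimensional series of steps 0 to `T`. Channel 2 is a
#' standard-normal data stream, zeroed over the last five steps
#' (`T-4`, ..., `T`). Channel 1 is a marker channel: `+1` at the five
#' relevant steps \eqn{t_1 < \dots < t_5}, `0` at step `T - 4` (the cue that
#' predictions now count), and `-1` everywhere else. The five relevant steps
#' are drawn uniformly without replacement from \eqn{\{0, \dots, T-N-1\}}
#' and sorted, so all relevant inputs fall strictly before step `T - N`:
#' `N` is the length of the forgetting period during which nothing relevant
#' appears. The targets are the five stored data values
#' \eqn{x_{t_1}[2], \dots, x_{t_5}[2]}, to be emitted in temporal order at
#' steps `T-4`, ..., `T`.
#'
#' @param T number of time steps after the initial one (`T >= 10`).
#' @param N forgetting-period length, in `5, ..., T - 4`.
#' @inheritParams gen_copy
#' @return a `"benchmark_data"` list with `X` (`n x (T+1) x 2`), `y`
#'   (`n x 5` target matrix), `task = "denoise"`, and `meta` including the
#'   `n x 5` matrix `t_rel` of relevant steps (0-based).
#' @export
#' @examples
#' d <- gen_denoise(T = 20, N = 5, n = 2, seed = 1)
#' d$meta$t_rel
gen_denoise <- function(T, N, n, seed = 0) {
  if (T < 10) stop("T must be >= 10", call. = FALSE)
  if (N < 5 || N > T - 5) {
    # five distinct relevant steps must fit strictly before T - N
    stop(sprintf("N must lie in {5, ..., T - 5} = {5, ..., %d}", T - 5),
      call. = FALSE)
  }
  stopifnot(n >= 1)
  gen <- function() {
    X <- array(0, dim = c(n, T + 1, 2))
    data_stream <- matrix(rnorm(n * (T + 1)), n, T + 1)
    data_stream[, (T - 3):(T + 1)] <- 0 # steps T-4 .. T (1-based T-3 .. T+1)
    t_rel <- t(vapply(seq_len(n), function(i) {
      sort(sample.int(T - N, 5L) - 1L) # uniform without replacement in {0,...,T-N-1}
    }, integer(5)))
    marker <- matrix(-1, n, T + 1)
    for (i in seq_len(n)) marker[i, t_rel[i, ] + 1L] <- 1
    marker[, T - 3] <- 0 # step T-4: the output cue wins
    X[, , 1] <- marker
    X[, , 2] <- data_stream
    y <- t(vapply(seq_len(n), function(i) data_stream[i, t_rel[i, ] + 1L],
                  numeric(5)))
    list(X = X, y = y, t_rel = t_rel)
  }
  g <- withr::with_seed(seed, gen())
  structure(
    list(X = g$X, y = g$y, task = "denoise",
         meta = list(T = T, N = N, n = n, seed = seed, t_rel = g$t_rel)),
    class = "benchmark_data"
  )
}

#' @export
print.benchmark_data <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<benchmark_data> task %s: %d samples x %d steps x %d channel(s)\n",
              x$task, d[1], d[2], d[3]))
  invisible(x)
}

#' Denoising-benchmark error
#'
#' The error of the denoising task: squared differences between the five
#' stored values and the network outputs at the five final steps, averaged
#' over the five outputs (and over samples when matrices are given).
#'
#' @param outputs,targets numeric vectors of length 5, or `n x 5` matrices.
#' @return scalar mean squared error.
#' @export
#' @examples
#' denoise_loss(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1)) # 1
denoise_loss <- function(outputs, targets) {
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  stopifnot(ncol(outputs) == 5, ncol(targets) == 5,
            nrow(outputs) == nrow(targets))
  mean(rowMeans((outputs - targets)^2))
}

#' Persist and reload benchmark datasets
#'
#' Datasets are written as R serialized objects (`.rds`) wrapped with a
#' format tag and validated on read, so a truncated or foreign file fails
#' with a clear error rather than producing a corrupt dataset.
#'
#' @param data a `"benchmark_data"` object.
#' @param path file path (conventionally ending in `.rds`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the dataset.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "benchmark_data"))
  saveRDS(list(format = "bistablernn-benchmark", version = 1L, data = data),
          path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("'%s' is not a readable dataset file: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "bistablernn-benchmark")) {
    stop(sprintf("'%s' is not a bistablernn benchmark dataset", path),
      call. = FALSE)
  }
  obj$data
}
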