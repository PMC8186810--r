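# Sequential-MNIST transforms. MNIST itself is an optional external input
# (standard IDX files, not downloaded by this package); all transforms work
# on any image matrix, and the tests exercise them on synthetic images.

#' Read an IDX-format array (MNIST images or labels)
#'
#' Parses the standard big-endian IDX binary format used to distribute
#' MNIST: a magic number declaring the element type and rank, the dimension
#' sizes, then the raw data. Images are returned as an
#' `n x rows x cols` array scaled to `[0, 1]`; labels as an integer vector.
#'
#' @param path path to an (uncompressed) IDX file.
#' @return integer vector (rank-1 files) or numeric array.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (is.na(magic) || bitwAnd(magic, -65536L) != 0L) {
    stop(sprintf("'%s' is not an IDX file (bad magic number)", path),
      call. = FALSE)
  }
  type <- bitwAnd(bitwShiftR(magic, 8L), 255L)
  ndim <- bitwAnd(magic, 255L)
  if (type != 8L) stop("only unsigned-byte IDX files are supported", call. = FALSE)
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  n <- prod(dims)
  raw_vals <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(raw_vals) != n) stop("truncated IDX file", call. = FALSE)
  if (ndim == 1L) {
    as.integer(raw_vals)
  } else {
    # row-major on disk -> fill the array accordingly, pixels scaled to [0, 1]
    aperm(array(raw_vals / 255, dim = rev(dims)), rev(seq_len(ndim)))
  }
}

#' Fixed pixel permutation shared across a dataset
#'
#' `make_pixel_permutation()` draws one permutation of the pixel positions;
#' `permute_pixels()` applies it to an image (flattened row by row). The
#' permuted-MNIST benchmarks use a single permutation for every image of the
#' dataset, so pixels that are neighbours in the image can end up far apart
#' in the sequence, making time dependencies long and unstructured.
#'
#' @param n_pixels number of pixel positions (784 for MNIST).
#' @param seed integer seed; the same seed gives the same permutation.
#' @return `make_pixel_permutation()`: an integer permutation vector.
#' @export
#' @examples
#' p <- make_pixel_permutation(9, seed = 1)
#' img <- matrix(1:9 / 9, 3, 3)
#' all.equal(permute_pixels(permute_pixels(img, p), invert_permutation(p)), img)
make_pixel_permutation <- function(n_pixels = 784L, seed = 0) {
  withr::with_seed(seed, sample.int(n_pixels))
}

#' @rdname make_pixel_permutation
#' @param image a numeric matrix (e.g. 28 x 28).
#' @param perm a permutation vector from [make_pixel_permutation()], or an
#'   integer seed from which one is drawn.
#' @return `permute_pixels()`: the permuted image, same dimensions.
#' @export
permute_pixels <- function(image, perm) {
  stopifnot(is.matrix(image))
  if (length(perm) == 1L) perm <- make_pixel_permutation(length(image), perm)
  stopifnot(length(perm) == length(image))
  flat <- as.vector(t(image))      # row-major flattening, as pixels are fed
  matrix(flat[perm], nrow(image), ncol(image), byrow = TRUE)
}

#' @rdname make_pixel_permutation
#' @param perm a permutation vector.
#' @return `invert_permutation()`: the inverse permutation.
#' @export
invert_permutation <- function(perm) order(perm)

#' Turn an image into a line-by-line input sequence
#'
#' Feeds an image to a recurrent network one row (line) at a time, giving an
#' input dimension equal to the image width (28 for MNIST). `n_black`
#' all-zero lines are appended at the bottom as a forgetting period: the
#' class-relevant content moves further from the prediction step. When
#' `marker` is set, one final line with every entry at `marker_value` is
#' appended; the value is strictly above the white-pixel value 1, so such a
#' line can never occur in a real image and unambiguously cues the network
#' to emit its class prediction at that step (used by the variable-length
#' variant, where the prediction step differs per sample).
#'
#' @param image a numeric matrix, rows = lines.
#' @param n_black number of all-zero lines appended after the image.
#' @param marker append a marker line?
#' @param marker_value value filling the marker line (default 2, above the
#'   white-pixel value 1).
#' @return a `(nrow(image) + n_black + marker) x ncol(image)` matrix.
#' @export
#' @examples
#' nrow(to_line_sequence(matrix(0, 28, 28), n_black = 72))       # 100
#' nrow(to_line_sequence(matrix(0, 28, 28), n_black = 472))      # 500
to_line_sequence <- function(image, n_black = 0, marker = FALSE,
                             marker_value = 2) {
  stopifnot(is.matrix(image), n_black >= 0)
  out <- rbind(image, matrix(0, n_black, ncol(image)))
  if (marker) out <- rbind(out, matrix(marker_value, 1, ncol(image)))
  out
}

#' Sample the number of padding lines for the variable-length variant
#'
#' Draws `n` values uniformly from the integers `{0, ..., X}`, the
#' per-sample number of black padding lines in the variable-line-sequential
#' benchmark.
#'
#' @param X upper bound (inclusive).
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of length `n` with values in `[0, X]`.
#' @export
sample_variable_padding <- function(X, n = 1, seed = 0) {
  stopifnot(X >= 0, n >= 1)
  withr::with_seed(seed, sample.int(X + 1L, n, replace = TRUE) - 1L)
}

#' Assemble a line-sequential classification dataset from images
#'
#' Applies one shared pixel permutation, converts each image to a line
#' sequence with (fixed or per-sample uniform) black-line padding and an
#' optional marker line, and zero-pads all sequences to a common length with
#' each sample's own prediction step recorded, so variable-length batches
#' can be trained with the loss taken at the right step.
#'
#' @param images `n x rows x cols` array (e.g. from [read_idx()]).
#' @param labels integer class labels (any coding; factor levels are used).
#' @param n_black fixed number of black lines, or `NULL` to sample per
#'   sample.
#' @param X upper bound for per-sample uniform padding (used when
#'   `n_black = NULL`).
#' @param marker append a marker line to every sequence?
#' @param permute permute pixels with a shared permutation?
#' @param seed integer seed driving the permutation and the padding draws.
#' @return a `"benchmark_data"` list with `X` (`n x max_len x cols`), `y`
#'   (integer labels in `1..K`), `out_step` (per-sample prediction step),
#'   `lengths`, `task = "classification"`.
#' @export
make_line_mnist <- function(images, labels, n_black = 0, X = NULL,
                            marker = FALSE, permute = TRUE, seed = 0) {
  stopifnot(length(dim(images)) == 3, dim(images)[1] == length(labels))
  n <- dim(images)[1]; rows <- dim(images)[2]; cols <- dim(images)[3]
  perm <- if (permute) make_pixel_permutation(rows * cols, seed)
  pad <- if (is.null(n_black)) {
    sample_variable_padding(X, n, seed = seed + 1L)
  } else rep(n_black, n)
  lens <- rows + pad + as.integer(marker)
  max_len <- max(lens)
  Xarr <- array(0, dim = c(n, max_len, cols))
  for (i in seq_len(n)) {
    img <- matrix(images[i, , ], rows, cols)
    if (permute) img <- permute_pixels(img, perm)
    seq_i <- to_line_sequence(img, n_black = pad[i], marker = marker)
    Xarr[i, seq_len(nrow(seq_i)), ] <- seq_i
  }
  y <- as.integer(factor(labels))
  structure(
    list(X = Xarr, y = y, out_step = lens, lengths = lens,
         task = "classification",
         meta = list(n = n, n_black = n_black, X = X, marker = marker,
                     permute = permute, seed = seed)),
    class = "benchmark_data"
  )
}
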