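test_that("parameter counts match the closed-form formulas", {
  d <- 3; n1 <- 8; n2 <- 6; out <- 2
  counts <- list(
    brc  = function(din, n) 3 * din * n + 2 * n + 3 * n,
    nbrc = function(din, n) 3 * din * n + 2 * n^2 + 3 * n,
    gru  = function(din, n) 3 * din * n + 3 * n^2 + 3 * n
  )
  for (cell in names(counts)) {
    m <- build_network(cell, d, c(n1, n2), out, "classification", seed = 1)
    expected <- counts[[cell]](d, n1) + counts[[cell]](n1, n2) + n2 * out + out
    expect_equal(n_params(m), expected)
  }
})

test_that("network construction is seed-deterministic; readout is affine", {
  m1 <- build_network("nbrc", 1, c(5, 4), 1, "regression-last", seed = 7)
  m2 <- build_network("nbrc", 1, c(5, 4), 1, "regression-last", seed = 7)
  expect_equal(m1, m2)
  # zero readout weights give a constant (zero) prediction
  m1$readout$V[] <- 0; m1$readout$b[] <- 0
  d <- gen_copy(6, 5, seed = 1)
  expect_true(all(predict(m1, d) == 0))
})

test_that("regression evaluation matches its definition", {
  d <- gen_copy(5, 40, seed = 2)
  m <- build_network("brc", 1, c(4, 4), 1, "regression-last", seed = 3)
  pred <- predict(m, d)
  expect_equal(evaluate_regression(m, d), mean((pred - d$y)^2))
  # an untrained (weak random readout) network scores near chance level 1
  big <- gen_copy(50, 10000, seed = 4)
  m2 <- build_network("nbrc", 1, c(32, 32), 1, "regression-last", seed = 5)
  expect_equal(evaluate_regression(m2, big), 1, tolerance = 0.05)
  # the denoising evaluation equals denoise_loss of the predictions
  dd <- gen_denoise(20, 5, 30, seed = 6)
  m3 <- build_network("nbrc", 2, c(4, 4), 1, "regression-last5", seed = 7)
  expect_equal(evaluate_regression(m3, dd),
               denoise_loss(predict(m3, dd), dd$y))
})

test_that("classification metrics: accuracy and macro F1 closed forms", {
  # all-correct predictor
  expect_equal(macro_f1(c(1, 2, 3), c(1, 2, 3), 3), 1)
  # single-class predictor on balanced 10-class data
  truth <- rep(1:10, each = 10)
  pred <- rep(1L, 100)
  expect_equal(mean(pred == truth), 0.1)
  expect_equal(macro_f1(pred, truth, 10), (2 * 0.1 / 1.1) / 10,
               tolerance = 1e-12)
  # permuting class labels leaves macro F1 unchanged
  set.seed(8)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(macro_f1(perm[pred], perm[truth], 4), macro_f1(pred, truth, 4))
})

test_that("training is deterministic per seed and aborts on divergence", {
  tr <- gen_copy(5, 200, seed = 1)
  te <- gen_copy(5, 100, seed = 2)
  m <- build_network("nbrc", 1, c(6, 6), 1, "regression-last", seed = 4)
  f1 <- train_network(m, tr, te, epochs = 2, batch_size = 50, seed = 9)
  f2 <- train_network(m, tr, te, epochs = 2, batch_size = 50, seed = 9)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$history, f2$history)
  expect_false(f1$diverged)
  # a non-finite loss is flagged and the run aborted
  mbad <- m
  mbad$readout$V[1] <- NaN
  expect_warning(
    fbad <- train_network(mbad, tr, te, epochs = 3, batch_size = 50, seed = 1),
    "diverged"
  )
  expect_true(fbad$diverged)
})

test_that("every cell kind learns the short-horizon copy task", {
  tr <- gen_copy(5, 2000, seed = 31)
  te <- gen_copy(5, 500, seed = 32)
  for (cell in c("brc", "nbrc", "gru")) {
    m <- build_network(cell, 1, c(32, 32), 1, "regression-last", seed = 0)
    f <- train_network(m, tr, te, epochs = 40, batch_size = 100, seed = 0,
                       eval_every = 0)
    expect_lt(f$metrics["mse"], 0.05)
  }
})

test_that("variable-length classification trains end to end", {
  set.seed(44)
  images <- array(runif(60 * 8 * 8), c(60, 8, 8))
  # make classes separable: class k has its k-th row amplified
  labels <- rep(1:3, each = 20)
  for (i in 1:60) images[i, labels[i] * 2, ] <- images[i, labels[i] * 2, ] + 2
  d <- make_line_mnist(images, labels, n_black = NULL, X = 4, marker = TRUE,
                       permute = FALSE, seed = 5)
  m <- build_network("nbrc", 8, c(12, 12), 3, "classification", seed = 1)
  f <- train_network(m, d, d, epochs = 15, batch_size = 20, seed = 1,
                     eval_every = 0)
  expect_false(f$diverged)
  expect_true(all(f$metrics >= 0 & f$metrics <= 1))
  expect_gt(f$metrics[["accuracy"]], 0.5) # learns separable classes
  expect_named(f$metrics, c("accuracy", "macro_f1"))
})

test_that("dataset/task mismatches are rejected", {
  dd <- gen_denoise(20, 5, 10, seed = 1)
  m <- build_network("brc", 1, c(4, 4), 1, "regression-last", seed = 1)
  expect_error(train_network(m, dd, epochs = 1), "task|dimension")
})

test_that("tidiers expose history and summary tables", {
  tr <- gen_copy(5, 100, seed = 1)
  te <- gen_copy(5, 50, seed = 2)
  res <- train_protocol("brc", c(4, 4), tr, te, seeds = c(0, 1), epochs = 2,
                        batch_size = 50)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 2) # one mse row per seed
  g <- glance(res)
  expect_equal(g$n_seeds, 2)
  expect_true(is.finite(g$mse_mean) && g$mse_sd >= 0)
  f <- res$fits[[1]]
  expect_true(all(c("epoch", "split", "metric", "value") %in% names(tidy(f))))
  expect_s3_class(glance(f), "tbl_df")
})
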