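test_that("BRC gates sit at their neutral values for zero weights", {
  w <- zero_weights("brc", 2, 4)
  g <- brc_gates(c(1.3, -0.2), rep(0.7, 4), w)
  expect_equal(g$a, rep(1, 4))
  expect_equal(g$c, rep(0.5, 4))
  wn <- zero_weights("nbrc", 2, 4)
  gn <- nbrc_gates(c(1.3, -0.2), rep(0.7, 4), wn)
  expect_equal(gn$a, rep(1, 4))
  expect_equal(gn$c, rep(0.5, 4))
})

test_that("feedback gate hits prescribed values and saturates inside (0, 2)", {
  # pre-activation atanh(0.5) gives a = 1.5 exactly
  w <- zero_weights("brc", 1, 1)
  w$b_a <- atanh(0.5)
  expect_equal(brc_gates(0, 0, w)$a, 1.5, tolerance = 1e-12)
  # strictly monotone approach to the endpoints while still resolvable
  for (pre in c(-15, -5, 5, 15)) {
    w$b_a <- pre
    a <- brc_gates(0, 0, w)$a
    expect_gt(a, 0); expect_lt(a, 2)
  }
  # beyond ~19 the gap to the endpoint falls below double-precision eps:
  # the supremum of attainable values converges to (and prints as) 2
  w$b_a <- 50
  expect_equal(brc_gates(0, 0, w)$a, 2, tolerance = 1e-15)
})

test_that("gate ranges hold over many random draws (BRC and nBRC)", {
  set.seed(42)
  for (cell in c("brc", "nbrc")) {
    gates_fn <- if (cell == "brc") brc_gates else nbrc_gates
    n_draws <- 0
    for (rep in 1:10) {
      w <- init_weights(cell, 3, 50, seed = rep)
      x <- matrix(rnorm(200 * 3), 200, 3)
      h <- matrix(runif(200 * 50, -1, 1), 200, 50)
      g <- gates_fn(x, h, w)
      expect_true(all(g$a > 0 & g$a < 2))
      expect_true(all(g$c > 0 & g$c < 1))
      n_draws <- n_draws + length(g$a)
    }
    expect_gte(n_draws, 1e5)
  }
})

test_that("BRC step follows the update rule exactly", {
  # zero everything: the origin is a fixed point
  w <- zero_weights("brc", 1, 3)
  expect_equal(brc_step(0, rep(0, 3), w), rep(0, 3))
  # frozen gates a = 1.5, c = 0.5, zero input drive, h = 0.5
  w1 <- frozen_brc(a = 1.5, c = 0.5)
  h1 <- brc_step(0, 0.5, w1)
  expect_equal(h1, 0.5 * 0.5 + 0.5 * tanh(1.5 * 0.5), tolerance = 1e-12)
})

test_that("iterates from opposite signs latch onto two distinct stable limits", {
  w <- frozen_brc(a = 1.5, c = 0.5)
  hp <- 0.5; hm <- -0.5
  for (t in 1:500) {
    hp <- brc_step(0, hp, w)
    hm <- brc_step(0, hm, w)
  }
  expect_gt(hp, 0.5)
  expect_lt(hm, -0.5)
  expect_equal(hp, -hm, tolerance = 1e-9) # symmetric branches
})

test_that("state stays in [-1, 1] whenever it starts there (boundedness)", {
  set.seed(7)
  for (cell in c("brc", "nbrc")) {
    step_fn <- switch(cell, brc = brc_step, nbrc = nbrc_step)
    w <- init_weights(cell, 2, 6, seed = 9)
    for (nm in names(w)) w[[nm]] <- w[[nm]] * 10 # extreme weights
    h <- runif(6, -1, 1)
    for (t in 1:100) {
      h <- step_fn(rnorm(2, sd = 5), h, w)
      expect_true(all(abs(h) <= 1))
    }
  }
})

test_that("BRC state Jacobian is diagonal: neurons never mix through h", {
  set.seed(11)
  w <- init_weights("brc", 2, 5, seed = 5)
  x <- rnorm(2)
  h0 <- runif(5, -0.8, 0.8)
  eps <- 1e-6
  J <- sapply(1:5, function(j) {
    hp <- h0; hp[j] <- hp[j] + eps
    hm <- h0; hm[j] <- hm[j] - eps
    (brc_step(x, hp, w) - brc_step(x, hm, w)) / (2 * eps)
  })
  offdiag <- J - diag(diag(J))
  expect_lt(max(abs(offdiag)), 1e-6)
  # nBRC gates mix neurons, so its Jacobian is generally NOT diagonal
  wn <- init_weights("nbrc", 2, 5, seed = 5)
  Jn <- sapply(1:5, function(j) {
    hp <- h0; hp[j] <- hp[j] + eps
    hm <- h0; hm[j] <- hm[j] - eps
    (nbrc_step(x, hp, wn) - nbrc_step(x, hm, wn)) / (2 * eps)
  })
  expect_gt(max(abs(Jn - diag(diag(Jn)))), 1e-6)
})

test_that("nBRC with diagonal kernels reduces exactly to the BRC", {
  set.seed(3)
  wb <- init_weights("brc", 3, 6, seed = 21)
  wn <- init_weights("nbrc", 3, 6, seed = 22)
  wn$U <- wb$U; wn$U_a <- wb$U_a; wn$U_c <- wb$U_c
  wn$W_a <- diag(wb$w_a); wn$W_c <- diag(wb$w_c)
  wn$b_a <- wb$b_a; wn$b_c <- wb$b_c; wn$b <- wb$b
  for (rep in 1:20) {
    x <- rnorm(3); h <- runif(6, -1, 1)
    gb <- brc_gates(x, h, wb); gn <- nbrc_gates(x, h, wn)
    expect_equal(gn$a, gb$a, tolerance = 1e-12)
    expect_equal(gn$c, gb$c, tolerance = 1e-12)
    expect_equal(nbrc_step(x, h, wn), brc_step(x, h, wb), tolerance = 1e-12)
  }
  # identity W_a with zero input leaves the feedback gate at 1 only at h = 0
  wn2 <- zero_weights("nbrc", 3, 6)
  wn2$W_a <- diag(6)
  expect_equal(nbrc_gates(rep(0, 3), rep(0, 6), wn2)$a, rep(1, 6))
})

test_that("GRU step obeys its gating limits", {
  w <- zero_weights("gru", 2, 4)
  expect_equal(gru_step(c(0, 0), rep(0, 4), w), rep(0, 4))
  # z -> 1: state is carried over unchanged
  w1 <- zero_weights("gru", 2, 4)
  w1$b_z <- rep(50, 4)
  h <- runif(4, -1, 1)
  expect_equal(gru_step(rnorm(2), h, w1), h, tolerance = 1e-12)
  # z -> 0, r -> 1: pure candidate tanh(U_h x + W_h h)
  set.seed(8)
  w2 <- init_weights("gru", 2, 4, seed = 2)
  w2$b_z <- rep(-50, 4); w2$b_r <- rep(50, 4)
  x <- rnorm(2)
  expected <- tanh(drop(x %*% w2$U_h + h %*% w2$W_h) + w2$b_h)
  expect_equal(gru_step(x, h, w2), expected, tolerance = 1e-10)
})

test_that("unroll stacks layers, records gates, and is deterministic", {
  layers <- list(init_weights("nbrc", 1, 5, seed = 1),
                 init_weights("nbrc", 5, 4, seed = 2))
  x <- matrix(rnorm(12), 12, 1)
  tr1 <- unroll(layers, x, record_gates = TRUE)
  tr2 <- unroll(layers, x, record_gates = TRUE)
  expect_identical(tr1$trajectory, tr2$trajectory)
  expect_identical(tr1$gates, tr2$gates)
  expect_equal(dim(tr1$trajectory[[1]]), c(12, 5))
  expect_equal(dim(tr1$gates[[2]]$a), c(12, 4))
  expect_equal(tr1$final[[2]], tr1$trajectory[[2]][12, ])
  # zero-weight single layer: all states stay at 0
  tr0 <- unroll(list(zero_weights("brc", 1, 3)), x)
  expect_true(all(tr0$trajectory[[1]] == 0))
  # errors: empty sequence, layer dimension mismatch
  expect_error(unroll(layers, matrix(numeric(0), 0, 1)), "empty")
  bad <- list(init_weights("nbrc", 1, 5, seed = 1),
              init_weights("nbrc", 7, 4, seed = 2))
  expect_error(unroll(bad, x), "input_dim")
  expect_error(brc_gates(c(1, 2, 3), rep(0, 5), init_weights("brc", 2, 5)),
               "length|columns")
})

test_that("a single bistable neuron latches a pulse; a monostable one forgets", {
  pulse <- c(rep(1, 5), rep(0, 60))
  latch <- frozen_brc(a = 1.5, c = 0.5)
  latch$U[] <- 1 # let the input drive the candidate
  tr <- unroll(list(latch), matrix(pulse, ncol = 1))
  expect_gt(abs(tr$final[[1]]), 0.5) # still holding the bit
  forget <- frozen_brc(a = 0.5, c = 0.5)
  forget$U[] <- 1
  tr2 <- unroll(list(forget), matrix(pulse, ncol = 1))
  expect_gt(abs(tr2$trajectory[[1]][5, 1]), 0.3) # driven during the pulse
  expect_lt(abs(tr2$final[[1]]), 1e-4) # relaxed back to the origin
})

test_that("initialization is seed-reproducible and respects gate ranges", {
  w1 <- init_weights("nbrc", 4, 8, seed = 123)
  w2 <- init_weights("nbrc", 4, 8, seed = 123)
  w3 <- init_weights("nbrc", 4, 8, seed = 124)
  expect_identical(unclass(w1)[names(w1)], unclass(w2)[names(w2)])
  expect_false(identical(w1$U, w3$U))
  # biases are zero at init, so the printed update equations hold exactly
  expect_true(all(w1$b_a == 0) && all(w1$b_c == 0) && all(w1$b == 0))
  # no-bias variant drops them altogether
  wnb <- init_weights("brc", 4, 8, seed = 1, bias = FALSE)
  expect_null(wnb$b_a)
  set.seed(99)
  g <- nbrc_gates(matrix(rnorm(50 * 4), 50, 4),
                  matrix(runif(50 * 8, -1, 1), 50, 8), w1)
  expect_true(all(g$a > 0 & g$a < 2) && all(g$c > 0 & g$c < 1))
})
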