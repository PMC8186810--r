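test_that("the scalar map and its derivative are exact", {
  expect_equal(map_rhs(0, a = 1.3, c = 0.4, u = 0), 0)
  expect_equal(map_rhs(0.5, a = 2, c = 0, u = 0), tanh(1.0))
  expect_equal(map_rhs(0.37, a = 0.9, c = 1), 0.37) # c = 1: identity map
  # derivative at the origin is c + (1 - c) a, the linearized gain
  for (cc in c(0, 0.25, 0.5, 0.9)) {
    for (a in c(0.3, 1, 1.7)) {
      expect_equal(map_derivative(0, a, cc), cc + (1 - cc) * a,
                   tolerance = 1e-14)
    }
  }
  # central finite difference of the map matches the analytic derivative
  set.seed(2)
  for (rep in 1:20) {
    a <- runif(1, 0, 2); cc <- runif(1); u <- rnorm(1); h <- runif(1, -1, 1)
    fd <- (map_rhs(h + 1e-5, a, cc, u) - map_rhs(h - 1e-5, a, cc, u)) / 2e-5
    expect_equal(map_derivative(h, a, cc, u), fd, tolerance = 1e-8)
  }
  expect_error(map_rhs(0, a = -1, c = 0.5), "a must")
  expect_error(map_rhs(0, a = 1, c = 2), "c must")
})

test_that("fixed-point structure: one stable point below gain 1, three above", {
  fp <- find_fixed_points(a = 0.5, c = 0.5)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$h_star, 0, tolerance = 1e-9)
  expect_equal(fp$stability, "stable")

  fp3 <- find_fixed_points(a = 1.5, c = 0.5)
  expect_equal(nrow(fp3), 3)
  expect_equal(sum(fp3$stability == "stable"), 2)
  expect_equal(sum(fp3$stability == "unstable"), 1)
  expect_equal(fp3$h_star[2], 0, tolerance = 1e-9) # unstable origin
  expect_equal(fp3$h_star[1], -fp3$h_star[3], tolerance = 1e-9) # symmetry

  # the stable branch agrees with long-run iteration of the map itself
  h <- 0.5
  for (t in 1:2000) h <- map_rhs(h, 1.5, 0.5)
  expect_equal(max(fp3$h_star), h, tolerance = 1e-8)
})

test_that("fixed-point count is odd with stable = unstable + 1, and scan matches iteration", {
  set.seed(31)
  for (rep in 1:25) {
    a <- runif(1, 0, 2); cc <- runif(1, 0, 0.95); u <- rnorm(1, sd = 0.3)
    fp <- find_fixed_points(a, cc, u)
    n_st <- sum(fp$stability == "stable")
    n_un <- sum(fp$stability == "unstable")
    if (any(fp$stability == "singular")) next # measure-zero marginal case
    expect_true(nrow(fp) %in% c(1L, 3L))
    expect_equal(n_st, n_un + 1)
    expect_true(all(abs(fp$h_star) < 1 + abs(u)))
    # attractors of 1e4-step iteration from 51 starts coincide with the
    # scanned stable points
    h <- seq(-1, 1, length.out = 51)
    for (t in 1:10000) h <- map_rhs(h, a, cc, u)
    attractors <- sort(unique(round(h, 6)))
    stable <- sort(fp$h_star[fp$stability == "stable"])
    expect_equal(length(attractors), length(stable))
    expect_lt(max(abs(attractors - stable)), 1e-6)
  }
})

test_that("all fixed points satisfy the fixed-point equation to tolerance", {
  for (a in c(0.2, 0.999, 1.001, 1.8)) {
    fp <- find_fixed_points(a, c = 0.3, u = 0.1)
    G <- fp$h_star - map_rhs(fp$h_star, a, 0.3, 0.1)
    expect_lt(max(abs(G)), 1e-10)
  }
  expect_error(find_fixed_points(1.5, c = 1), "degenerate")
})

test_that("bifurcation diagram detects the pitchfork at gain 1 for any c", {
  for (cc in c(0, 0.25, 0.5, 0.9)) {
    bd <- bifurcation_diagram(c = cc, a_min = 0.9, a_max = 1.1, steps = 201,
                              grid_n = 801)
    expect_equal(attr(bd, "critical_a"), 1, tolerance = 1.1e-3)
  }
  # branch magnitude grows monotonically in a beyond the bifurcation
  bd <- bifurcation_diagram(c = 0.5, a_min = 0, a_max = 2, steps = 81)
  up <- bd |>
    dplyr::filter(.data$stability == "stable", .data$h_star > 1e-6) |>
    dplyr::arrange(.data$a)
  expect_true(all(diff(up$h_star) > 0))
  expect_gt(max(find_fixed_points(1.99, 0.5)$h_star),
            max(find_fixed_points(1.01, 0.5)$h_star))
  # odd symmetry of the u = 0 diagram
  sym <- bd |> dplyr::group_by(.data$a) |>
    dplyr::summarise(s = abs(sum(.data$h_star)), .groups = "drop")
  expect_lt(max(sym$s), 1e-8)
})

test_that("pitchfork conditions hold: four zeros, positive cubic, negative mixed term", {
  for (cc in c(0, 0.25, 0.5, 0.9)) {
    pc <- pitchfork_conditions(cc)
    expect_true(all(pc$satisfied))
    zeros <- pc$analytic[pc$requirement == "= 0"]
    expect_lt(max(abs(zeros)), 1e-12)
    expect_equal(pc$analytic[pc$condition == "d3G_dh3"], 2 * (1 - cc))
    expect_equal(pc$analytic[pc$condition == "d2G_dhda"], cc - 1)
    # the finite-difference cross-check agrees with the closed forms
    expect_lt(max(abs(pc$analytic - pc$numeric)), 1e-3)
  }
  pc0 <- pitchfork_conditions(0)
  expect_equal(pc0$analytic[pc0$condition == "d3G_dh3"], 2)
  expect_equal(pc0$analytic[pc0$condition == "d2G_dhda"], -1)
})

test_that("IV curve switches from one to three zeros as the gain crosses 1", {
  z1 <- attr(iv_curve(0.5), "zeros")
  expect_equal(length(z1), 1)
  expect_equal(z1, 0, tolerance = 1e-9)
  z3 <- attr(iv_curve(2), "zeros")
  expect_equal(length(z3), 3)
  expect_equal(z3[1], -z3[3], tolerance = 1e-9)
  # odd function
  cur <- iv_curve(1.7, v = seq(-2, 2, length.out = 401))
  expect_equal(cur$current, -rev(cur$current), tolerance = 1e-12)
  # monotone increasing for alpha <= 1
  c05 <- iv_curve(0.5)
  expect_true(all(diff(c05$current) > 0))
})

test_that("step response latches for a > 1 and relaxes for a < 1", {
  pulse <- c(rep(1, 10), rep(0, 500))
  tr <- step_response(a = 1.5, c = 0.9, input = pulse)
  h1 <- max(find_fixed_points(1.5, 0.9)$h_star)
  expect_equal(abs(tail(tr$h, 1)), h1, tolerance = 1e-6)
  tr0 <- step_response(a = 0.5, c = 0.9, input = pulse)
  expect_lt(abs(tail(tr0$h, 1)), 1e-6)
  # zero input from the origin stays identically zero
  trz <- step_response(a = 1.5, c = 0.5, input = rep(0, 20))
  expect_true(all(trz$h == 0))
})

test_that("a bistable state holds its branch essentially forever", {
  # never-fading memory: on the stable branch the state stays put
  for (cc in c(0.1, 0.5, 0.9)) {
    h1 <- max(find_fixed_points(1.5, cc)$h_star)
    h <- h1
    for (it in 1:1e6) h <- cc * h + (1 - cc) * tanh(1.5 * h)
    expect_lt(abs(h - h1), 1e-9) # 1e6 iterations later
  }
})
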