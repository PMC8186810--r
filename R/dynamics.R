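#' The scalar bistable-cell map and its derivative
#'
#' For frozen gates, each neuron of a bistable recurrent cell iterates the
#' one-dimensional map
#' \deqn{h_{t} = F(h_{t-1}) = c\,h_{t-1} + (1 - c)\tanh(u + a\,h_{t-1}),}
#' where `a` is the feedback gain, `c` the update-gate value and `u` the
#' scalar input drive. `map_rhs()` evaluates \eqn{F}; `map_derivative()`
#' evaluates \eqn{F'(h) = c + (1 - c)\,a\,(1 - \tanh^2(u + a h))}, which at
#' the origin with `u = 0` reduces to \eqn{c + (1 - c) a}: the origin is
#' stable for `a < 1` and unstable for `a > 1`, independently of `c`.
#'
#' @param h state value(s); vectorized.
#' @param a feedback gain, `a >= 0`.
#' @param c update-gate value in `[0, 1]`.
#' @param u scalar input drive (default 0).
#' @return numeric vector of map (or derivative) values.
#' @export
#' @examples
#' map_rhs(0.5, a = 2, c = 0, u = 0)      # tanh(1)
#' map_derivative(0, a = 1.5, c = 0.5)    # c + (1 - c) a = 1.25
map_rhs <- function(h, a, c, u = 0) {
  check_map_params(a, c)
  c * h + (1 - c) * tanh(u + a * h)
}

#' @rdname map_rhs
#' @export
map_derivative <- function(h, a, c, u = 0) {
  check_map_params(a, c)
  c + (1 - c) * a * (1 - tanh(u + a * h)^2)
}

check_map_params <- function(a, c) {
  if (any(a < 0)) stop("feedback gain a must be >= 0", call. = FALSE)
  if (any(c < 0 | c > 1)) stop("update gate c must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Fixed points of the scalar cell map with stability labels
#'
#' Scans \eqn{G(h) = h - F(h)} for sign changes on a grid over
#' `[-1 - |u|, 1 + |u|]` (the map sends that interval into itself, so all
#' fixed points lie inside), refines each bracket by bisection, and labels
#' each root by the map derivative: stable if \eqn{F'(h^*) < 1}, unstable if
#' \eqn{> 1}, singular if within `1e-9` of 1 (the measure-zero marginal
#' case, reported rather than silently rounded).
#'
#' For `u = 0` the map has a single stable fixed point at the origin when
#' `a < 1`, and two symmetric stable points separated by the now-unstable
#' origin when `a > 1` — the supercritical pitchfork underlying bistable
#' cellular memory.
#'
#' @inheritParams map_rhs
#' @param grid_n number of grid points for the sign-change scan (>= 100).
#' @param tol bisection tolerance on `|G(h)|` and the bracket width.
#' @return a tibble of class `"fixed_points"` with columns `h_star`,
#'   `derivative`, `stability`; attributes `a`, `c`, `u`.
#' @export
#' @examples
#' find_fixed_points(a = 1.5, c = 0.5)
find_fixed_points <- function(a, c, u = 0, grid_n = 2001, tol = 1e-12) {
  check_map_params(a, c)
  stopifnot(grid_n >= 100)
  if (c >= 1) {
    stop("c = 1 is degenerate: the map is the identity and every h is fixed",
      call. = FALSE)
  }
  lim <- 1 + abs(u)
  grid <- seq(-lim, lim, length.out = grid_n)
  G <- function(h) h - map_rhs(h, a, c, u)
  g <- G(grid)
  roots <- grid[g == 0]
  sc <- which(g[-1] * g[-length(g)] < 0)
  for (i in sc) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      gm <- G(mid)
      if (abs(gm) < tol || (hi - lo) / 2 < tol) break
      if (sign(gm) == sign(G(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(roots)
  if (length(roots) > 1) { # merge near-duplicates from grid-point hits
    keep <- c(TRUE, diff(roots) > 1e-9)
    roots <- roots[keep]
  }
  deriv <- map_derivative(roots, a, c, u)
  stability <- ifelse(abs(deriv - 1) < 1e-9, "singular",
    ifelse(deriv < 1, "stable", "unstable"))
  out <- tibble::tibble(h_star = roots, derivative = deriv,
                        stability = stability)
  structure(out, a = a, c = c, u = u,
            class = c("fixed_points", class(out)))
}

#' Bifurcation diagram of the scalar cell map in the feedback gain
#'
#' Sweeps the feedback gain `a` over a grid at fixed `c` and `u`, collecting
#' all fixed points with their stability. For `u = 0` the diagram is the
#' supercritical pitchfork: a single stable branch at the origin for `a < 1`
#' splitting into two symmetric stable branches (with the origin unstable)
#' for `a > 1`. `critical_a` is the smallest swept `a` at which more than
#' one stable fixed point exists.
#'
#' @inheritParams map_rhs
#' @param a_min,a_max,steps sweep range and resolution for `a`.
#' @param grid_n passed to [find_fixed_points()].
#' @return a tibble of class `"bifurcation_diagram"` with columns `a`,
#'   `h_star`, `derivative`, `stability`, and attributes `critical_a`, `c`,
#'   `u`. Plot with [autoplot()].
#' @export
#' @examples
#' bd <- bifurcation_diagram(c = 0.5, steps = 101)
#' attr(bd, "critical_a")
bifurcation_diagram <- function(c, u = 0, a_min = 0, a_max = 2, steps = 401,
                                grid_n = 2001) {
  a_grid <- seq(a_min, a_max, length.out = steps)
  rows <- lapply(a_grid, function(a) {
    fp <- find_fixed_points(a, c, u, grid_n = grid_n)
    tibble::tibble(a = a, h_star = fp$h_star, derivative = fp$derivative,
                   stability = fp$stability)
  })
  out <- dplyr::bind_rows(rows)
  n_stable <- out |>
    dplyr::filter(.data$stability == "stable") |>
    dplyr::count(.data$a)
  crit <- n_stable$a[n_stable$n > 1]
  critical_a <- if (length(crit)) min(crit) else NA_real_
  structure(out, critical_a = critical_a, c = c, u = u,
            class = c("bifurcation_diagram", class(out)))
}

#' Numerical verification of the supercritical-pitchfork conditions
#'
#' The map \eqn{F} undergoes a supercritical pitchfork at the origin as the
#' feedback gain crosses \eqn{a_{pf} = 1}. With \eqn{G(h) = h - F(h)}, the
#' classical conditions at \eqn{(h, a) = (0, 1)} are: \eqn{G}, its first and
#' second h-derivatives, and its a-derivative all vanish; the third
#' h-derivative is positive (here \eqn{2(1 - c)}); and the mixed h,a
#' derivative is negative (here \eqn{c - 1}). This function evaluates all
#' six both from the closed forms and by high-order central finite
#' differences; the closed forms are authoritative, the finite differences
#' are an independent numerical cross-check.
#'
#' @param c update-gate value in `[0, 1)`.
#' @param h step size for the finite-difference cross-check.
#' @return a tibble with one row per condition: `condition`, `analytic`,
#'   `numeric` (finite difference), `requirement`, `satisfied`.
#' @export
#' @examples
#' pitchfork_conditions(c = 0.5)
pitchfork_conditions <- function(c, h = 1e-2) {
  stopifnot(c >= 0, c < 1)
  a_pf <- 1
  G <- function(x, a = a_pf) x - (c * x + (1 - c) * tanh(a * x))
  # closed forms at (h, a) = (0, 1)
  analytic <- c(
    G0      = (1 - c) * (0 - tanh(0)),
    dG_dh   = (1 - c) * (1 - a_pf),
    d2G_dh2 = (1 - c) * 2 * a_pf^2 * tanh(0) * (1 - tanh(0)^2),
    dG_da   = (1 - c) * 0 * (tanh(0)^2 - 1),
    d3G_dh3 = 2 * (1 - c),
    d2G_dhda = c - 1
  )
  # finite-difference cross-check
  fd <- c(
    G0 = G(0),
    dG_dh = (G(h) - G(-h)) / (2 * h),
    d2G_dh2 = (G(h) - 2 * G(0) + G(-h)) / h^2,
    dG_da = (G(0, a_pf + h) - G(0, a_pf - h)) / (2 * h),
    d3G_dh3 = (G(2 * h) - 2 * G(h) + 2 * G(-h) - G(-2 * h)) / (2 * h^3),
    d2G_dhda = ((G(h, a_pf + h) - G(-h, a_pf + h)) -
                  (G(h, a_pf - h) - G(-h, a_pf - h))) / (4 * h^2)
  )
  requirement <- c("= 0", "= 0", "= 0", "= 0", "> 0", "< 0")
  satisfied <- c(
    abs(analytic[1:4]) < 1e-12,
    analytic[5] > 0,
    analytic[6] < 0
  )
  tibble::tibble(
    condition = names(analytic),
    analytic = unname(analytic),
    numeric = unname(fd),
    requirement = requirement,
    satisfied = unname(satisfied)
  )
}

#' Neuronal IV curve with a tunable negative-slope region
#'
#' Evaluates the intrinsic current \eqn{I = v - \alpha \tanh(v)}, the
#' electrical-circuit model of a neuron's current-voltage relationship. For
#' \eqn{\alpha \le 1} the curve is monotonically increasing with a single
#' zero (monostable); for \eqn{\alpha > 1} a local negative-slope region
#' around the origin creates three zeros — two stable voltage states
#' separated by an unstable one (bistable). This is the biophysical picture
#' the feedback gate of the BRC mimics.
#'
#' @param alpha feedback gain (> 0); slope parameter of the nonlinearity.
#' @param v voltage grid.
#' @return a tibble of class `"iv_curve"` with columns `v`, `current`;
#'   attribute `zeros` holds the refined zero crossings. Plot with
#'   [autoplot()].
#' @export
#' @examples
#' attr(iv_curve(0.5), "zeros")  # one zero
#' attr(iv_curve(2), "zeros")    # three zeros
iv_curve <- function(alpha, v = seq(-3, 3, length.out = 601)) {
  stopifnot(alpha > 0)
  f <- function(x) x - alpha * tanh(x)
  current <- f(v)
  zeros <- v[current == 0]
  sc <- which(current[-1] * current[-length(current)] < 0)
  for (i in sc) {
    zeros <- c(zeros, uniroot(f, c(v[i], v[i + 1]), tol = 1e-12)$root)
  }
  zeros <- sort(zeros)
  if (length(zeros) > 1) zeros <- zeros[c(TRUE, diff(zeros) > 1e-9)]
  out <- tibble::tibble(v = v, current = current)
  structure(out, alpha = alpha, zeros = zeros,
            class = c("iv_curve", class(out)))
}

#' Step response of a single bistable neuron
#'
#' Iterates the scalar cell map under a piecewise input schedule. With a
#' feedback gain `a > 1`, a transient pulse latches the state onto a nonzero
#' stable branch where it remains after the input returns to zero
#' (never-fading memory); with `a < 1` the state relaxes back to the origin.
#' The update gate `c` sets the speed of either convergence.
#'
#' @param a,c feedback gain and update gate; scalars or vectors of
#'   `length(input)` for time-varying gates.
#' @param input numeric vector of input drives `u_t`, one per step.
#' @param h0 initial state (default 0).
#' @return a tibble with columns `step`, `input`, `h`.
#' @export
#' @examples
#' tr <- step_response(a = 1.5, c = 0.5, input = c(rep(1, 5), rep(0, 45)))
#' tail(tr$h, 1)  # latched near the upper stable branch
step_response <- function(a, c, input, h0 = 0) {
  n <- length(input)
  a <- rep_len(a, n); c <- rep_len(c, n)
  h <- numeric(n)
  prev <- h0
  for (t in seq_len(n)) {
    prev <- map_rhs(prev, a[t], c[t], input[t])
    h[t] <- prev
  }
  tibble::tibble(step = seq_len(n), input = input, h = h)
}
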