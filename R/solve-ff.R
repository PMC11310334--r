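#' Weights of the fractal-fractional product-integration scheme
#'
#' Two-point Lagrange interpolation of the kernel-weighted field on each
#' subinterval yields, for lag `n - ell`, the current-node weight
#' \eqn{(n+1-\ell)^\vartheta(n-\ell+2+\vartheta) -
#'      (n-\ell)^\vartheta(n+2+2\vartheta-\ell)}
#' and the previous-node weight
#' \eqn{(n-\ell+1)^{\vartheta+1} - (n-\ell)^\vartheta(n-\ell+1+\vartheta)}.
#' At `vartheta = 1` the pair reduces to the (3, 1)/2 stencil of the
#' classical two-step Adams-Bashforth method.
#'
#' @param n Step index.
#' @param ell Node index (vectorised), `0 <= ell <= n`.
#' @param vartheta Fractional order in (0, 1].
#' @return Numeric weight(s); the current-node weight is positive and the
#'   previous-node weight nonnegative.
#' @export
ff_weight_current <- function(n, ell, vartheta) {
  stopifnot(vartheta > 0, vartheta <= 1, n >= 0)
  if (any(ell < 0 | ell > n)) {
    rlang::abort("node index ell must lie in 0..n",
                 class = "fracdrink_index_error")
  }
  j <- n - ell
  (j + 1)^vartheta * (j + 2 + vartheta) - j^vartheta * (j + 2 + 2 * vartheta)
}

#' @rdname ff_weight_current
#' @export
ff_weight_previous <- function(n, ell, vartheta) {
  stopifnot(vartheta > 0, vartheta <= 1, n >= 0)
  if (any(ell < 0 | ell > n)) {
    rlang::abort("node index ell must lie in 0..n",
                 class = "fracdrink_index_error")
  }
  j <- n - ell
  (j + 1)^(vartheta + 1) - j^vartheta * (j + 1 + vartheta)
}

#' Solve a fractal-fractional (power-law) system by product integration
#'
#' Explicit two-point Lagrange product-integration scheme for the Caputo
#' fractal-fractional initial-value problem: the update is
#' \deqn{g_{n+1} = g_0 + \frac{\zeta h^\vartheta}{\Gamma(\vartheta+2)}
#'   \sum_{\ell=0}^{n}\left[t_\ell^{\zeta-1} F(t_\ell, g_\ell)\, w^{c}_{n-\ell}
#'   - t_{\ell-1}^{\zeta-1} F(t_{\ell-1}, g_{\ell-1})\, w^{p}_{n-\ell}\right].}
#' Two regularisations close the scheme at the left end of the grid: the
#' singular kernel factor \eqn{t_0^{\zeta-1}} (infinite for `zeta < 1`) is
#' evaluated one step in, as \eqn{h^{\zeta-1}}, and the `ell = 0` term's
#' undefined previous node takes the `ell = 0` values, which makes the first
#' step the fractional rectangle rule and the `vartheta = zeta = 1` limit the
#' classical Adams-Bashforth two-step method with an Euler start. At
#' `zeta = 1` the scheme is a pure Caputo product-integration rule and tracks
#' [solve_caputo()] on the same grid.
#'
#' @inheritParams solve_caputo
#' @param zeta Fractal order in (0, 1].
#' @return A `drink_trajectory` tibble.
#' @examples
#' traj <- solve_fractal_fractional(table1_parameters(), initial_conditions(),
#'                                  vartheta = 0.9, zeta = 0.9,
#'                                  t_end = 25, n_steps = 250)
#' tail(traj, 2)
#' @export
solve_fractal_fractional <- function(field, ic, vartheta = 1, zeta = 1,
                                     t_end, n_steps) {
  stopifnot(vartheta > 0, vartheta <= 1, zeta > 0, zeta <= 1,
            t_end > 0, n_steps >= 2)
  f <- resolve_field(field)
  y0 <- if (is.null(f$ynames)) as.numeric(ic) else unname(as_state(ic))
  d <- length(y0)
  ynames <- f$ynames %||% paste0("y", seq_len(d))
  N <- as.integer(n_steps)
  h <- t_end / N
  times <- h * (0:N)

  # lag-indexed weights: cw[j+1], pw[j+1] for j = n - ell
  jj <- 0:N
  cw <- (jj + 1)^vartheta * (jj + 2 + vartheta) -
    jj^vartheta * (jj + 2 + 2 * vartheta)
  pw <- (jj + 1)^(vartheta + 1) - jj^vartheta * (jj + 1 + vartheta)

  # kernel factor t_ell^(zeta-1); the singular ell = 0 factor is taken at the
  # first interior scale h^(zeta-1)
  tker <- times^(zeta - 1)
  tker[1L] <- h^(zeta - 1)

  pref <- zeta * h^vartheta / exp(lgamma(vartheta + 2))

  Y <- matrix(NA_real_, N + 1L, d)
  Y[1L, ] <- y0
  G <- matrix(NA_real_, N + 1L, d)      # current-node products t^(zeta-1) F
  Gp <- matrix(NA_real_, N + 1L, d)     # previous-node products, row ell+1
  G[1L, ] <- tker[1L] * as.numeric(f$fn(times[1L], stats::setNames(y0, ynames)))
  Gp[1L, ] <- G[1L, ]                   # ell = 0: previous node folded onto node 0

  for (n in 0:(N - 1L)) {
    idx <- 1:(n + 1L)
    wc <- cw[(n:0) + 1L]
    wp <- pw[(n:0) + 1L]
    ynew <- y0 + pref * (
      as.numeric(crossprod(G[idx, , drop = FALSE], wc)) -
      as.numeric(crossprod(Gp[idx, , drop = FALSE], wp)))
    check_finite_step(ynew, n + 1L)
    Y[n + 2L, ] <- ynew
    G[n + 2L, ] <- tker[n + 2L] *
      as.numeric(f$fn(times[n + 2L], stats::setNames(ynew, ynames)))
    Gp[n + 2L, ] <- G[n + 1L, ]
  }

  new_trajectory(times, Y, ynames, "fractal_fractional", vartheta, zeta,
                 f$params)
}
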