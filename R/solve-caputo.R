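#' Quadrature weights of the fractional Adams-Bashforth-Moulton scheme
#'
#' `corrector_weight()` returns the trapezoid-type product-integration weight
#' \eqn{\theta_{k,u+1}} of the corrector stage:
#' \eqn{u^{\vartheta+1} - (u-\vartheta)(u+1)^\vartheta} for `k = 0`,
#' \eqn{(u-k+2)^{\vartheta+1} + (u-k)^{\vartheta+1} - 2(u-k+1)^{\vartheta+1}}
#' for `1 <= k <= u`, and 1 for `k = u + 1`. At `vartheta = 1` these collapse
#' to the classical trapezoid stencil. `predictor_weight()` returns the
#' rectangle-rule weight
#' \eqn{b_{k,u+1} = (h^\vartheta/\vartheta)[(u-k+1)^\vartheta - (u-k)^\vartheta]};
#' its sum over `k = 0..u` telescopes to \eqn{t_{u+1}^\vartheta/\vartheta},
#' the total mass of the power-law kernel.
#'
#' @param k Node index (vectorised); `0 <= k <= u + 1` for the corrector,
#'   `0 <= k <= u` for the predictor.
#' @param u Step index.
#' @param vartheta Fractional order in (0, 1].
#' @param h Step size (predictor only).
#' @return Numeric weight(s), strictly positive.
#' @export
corrector_weight <- function(k, u, vartheta) {
  stopifnot(vartheta > 0, vartheta <= 1, u >= 0)
  if (any(k < 0 | k > u + 1)) {
    rlang::abort("corrector weight index k must lie in 0..(u+1)",
                 class = "fracdrink_index_error")
  }
  a <- vartheta + 1
  w <- numeric(length(k))
  w[k == 0] <- u^a - (u - vartheta) * (u + 1)^vartheta
  mid <- k >= 1 & k <= u
  j <- u - k[mid]
  w[mid] <- (j + 2)^a + j^a - 2 * (j + 1)^a
  w[k == u + 1] <- 1
  w
}

#' @rdname corrector_weight
#' @export
predictor_weight <- function(k, u, vartheta, h) {
  stopifnot(vartheta > 0, vartheta <= 1, u >= 0, h > 0)
  if (any(k < 0 | k > u)) {
    rlang::abort("predictor weight index k must lie in 0..u",
                 class = "fracdrink_index_error")
  }
  j <- u - k
  (h^vartheta / vartheta) * ((j + 1)^vartheta - j^vartheta)
}

#' @keywords internal
resolve_field <- function(field) {
  if (inherits(field, "drink_params")) {
    params <- field
    list(fn = function(t, y) drink_rhs(t, y, params),
         ynames = COMPARTMENTS, params = params)
  } else if (is.function(field)) {
    list(fn = field, ynames = NULL, params = NULL)
  } else {
    rlang::abort("`field` must be a drink_params object or a function(t, y)")
  }
}

#' @keywords internal
new_trajectory <- function(times, Y, ynames, solver, vartheta, zeta, params) {
  colnames(Y) <- ynames
  out <- tibble::as_tibble(as.data.frame(Y))
  out <- dplyr::bind_cols(tibble::tibble(t = times), out)
  attr(out, "solver") <- solver
  attr(out, "vartheta") <- vartheta
  attr(out, "zeta") <- zeta
  attr(out, "h") <- times[2L] - times[1L]
  attr(out, "params") <- params
  class(out) <- c("drink_trajectory", class(out))
  out
}

#' @keywords internal
check_finite_step <- function(y, u) {
  if (!all(is.finite(y))) {
    rlang::abort(paste0("solution became non-finite at step ", u),
                 class = "fracdrink_blowup")
  }
  y
}

#' Solve a Caputo fractional system by the Adams-Bashforth-Moulton scheme
#'
#' One-pass PECE predictor-corrector on the uniform grid `t_u = u*h`,
#' `h = t_end/n_steps`, with full memory (cost grows quadratically in the
#' number of steps). The predictor is the fractional rectangle rule; the
#' corrector applies the trapezoid-type weights once per step. The scheme has
#' convergence order `1 + vartheta` on the linear test problem and reduces to
#' a classical second-order predictor-corrector at `vartheta = 1`.
#'
#' @param field Either a `drink_params` object (solves the alcohol model) or
#'   a function `field(t, y)` returning the vector of rates.
#' @param ic Initial condition: for the alcohol model a named compartment
#'   vector (see [initial_conditions()]); otherwise any numeric vector.
#' @param vartheta Fractional order in (0, 1].
#' @param t_end Horizon.
#' @param n_steps Number of grid steps (at least 2).
#' @return A `drink_trajectory` tibble with column `t` and one column per
#'   state variable; solver metadata is stored in attributes.
#' @examples
#' traj <- solve_caputo(table1_parameters(), initial_conditions(),
#'                      vartheta = 0.9, t_end = 25, n_steps = 250)
#' tail(traj, 2)
#' @export
solve_caputo <- function(field, ic, vartheta = 1, t_end, n_steps) {
  stopifnot(vartheta > 0, vartheta <= 1, t_end > 0, n_steps >= 2)
  f <- resolve_field(field)
  y0 <- if (is.null(f$ynames)) as.numeric(ic) else unname(as_state(ic))
  d <- length(y0)
  ynames <- f$ynames %||% paste0("y", seq_len(d))
  N <- as.integer(n_steps)
  h <- t_end / N
  times <- h * (0:N)

  # precomputed first differences of j^vartheta and the interior corrector
  # second differences of j^(vartheta+1), indexed by lag j = u - k
  a <- vartheta + 1
  jj <- 0:(N + 1)
  d1 <- (jj[-1])^vartheta - (jj[-length(jj)])^vartheta   # d1[j+1] = (j+1)^v - j^v
  pa <- jj^a
  e2 <- pa[3:(N + 2)] + pa[1:N] - 2 * pa[2:(N + 1)]      # e2[j+1], j = 0..N-1

  cp <- h^vartheta / gamma(vartheta + 1)   # predictor prefactor
  cc <- h^vartheta / gamma(vartheta + 2)   # corrector prefactor

  Y <- matrix(NA_real_, N + 1L, d)
  Fh <- matrix(NA_real_, N + 1L, d)
  Y[1L, ] <- y0
  Fh[1L, ] <- f$fn(times[1L], stats::setNames(y0, ynames))

  for (u in 0:(N - 1L)) {
    idx <- 1:(u + 1L)
    bw <- d1[(u:0) + 1L]                                  # k = 0..u
    yp <- y0 + cp * as.numeric(crossprod(Fh[idx, , drop = FALSE], bw))
    theta0 <- u^a - (u - vartheta) * (u + 1)^vartheta
    tw <- if (u >= 1L) c(theta0, e2[((u - 1L):0) + 1L]) else theta0
    Fp <- f$fn(times[u + 2L], stats::setNames(yp, ynames))
    ynew <- y0 + cc * (as.numeric(Fp) +
      as.numeric(crossprod(Fh[idx, , drop = FALSE], tw)))
    check_finite_step(ynew, u + 1L)
    Y[u + 2L, ] <- ynew
    Fh[u + 2L, ] <- f$fn(times[u + 2L], stats::setNames(ynew, ynames))
  }

  new_trajectory(times, Y, ynames, "caputo_abm", vartheta, 1, f$params)
}

#' Solve the classical (integer-order) model with an adaptive integrator
#'
#' Thin wrapper around [deSolve::ode()] (lsoda) on the same output grid as
#' the fractional solvers; used as the high-accuracy reference for the
#' `vartheta = 1` limit.
#'
#' @inheritParams solve_caputo
#' @param rtol,atol Relative and absolute tolerances passed to the integrator.
#' @return A `drink_trajectory` tibble.
#' @export
solve_classical <- function(field, ic, t_end, n_steps,
                            rtol = 1e-10, atol = 1e-10) {
  stopifnot(t_end > 0, n_steps >= 2)
  f <- resolve_field(field)
  y0 <- if (is.null(f$ynames)) as.numeric(ic) else unname(as_state(ic))
  ynames <- f$ynames %||% paste0("y", seq_along(y0))
  times <- seq(0, t_end, length.out = as.integer(n_steps) + 1L)
  sol <- deSolve::ode(
    y = stats::setNames(y0, ynames), times = times,
    func = function(t, y, parms) list(as.numeric(f$fn(t, y))),
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol
  )
  new_trajectory(times, unname(sol[, -1L, drop = FALSE]), ynames,
                 "classical", 1, 1, f$params)
}
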