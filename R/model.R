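#' Derived rate constants and the basic reproduction number
#'
#' Computes the grouped outflow rates `q1..q5`, the equilibrium shape
#' constants `c1..c7`, and the threshold number
#' \deqn{R_0 = \frac{q_2\beta_1 + \psi\beta_2}{q_1 q_2},}
#' with `q1 = psi + nu` and
#' `q2 = nu + theta1 + theta2 + theta3 + delta1 + phi`.
#'
#' @param params A `drink_params` object.
#' @return A `drink_constants` object (named list with `q1..q5`, `c1..c7`,
#'   `R0`); use [tidy()] for a tibble.
#' @examples
#' derived_constants(table1_parameters())$R0
#' @export
derived_constants <- function(params) {
  p <- validate_drink_params(params)
  q1 <- p$psi + p$nu
  q2 <- p$nu + p$theta1 + p$theta2 + p$theta3 + p$delta1 + p$phi
  q3 <- p$nu + p$delta2 + p$gamma1
  q4 <- p$nu + p$delta3 + p$gamma2
  q5 <- p$nu + p$delta4 + p$gamma3
  c1 <- 1 / q1
  c2 <- p$psi / (q1 * q2)
  c3 <- p$psi * p$phi / (q1 * q2 * q3)
  c4 <- p$psi * p$theta1 / (q1 * q2 * q4)
  c5 <- p$psi * p$theta2 / (q1 * q2 * q5)
  c6 <- c2 * p$theta3 + c3 * p$gamma1 + c4 * p$gamma2 + c5 * p$gamma3
  c7 <- c1 + c2 + c3 + c4 + c5 + c6 / p$nu
  R0 <- (q2 * p$beta1 + p$psi * p$beta2) / (q1 * q2)
  structure(
    list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5,
         c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, c7 = c7,
         R0 = R0),
    class = "drink_constants"
  )
}

#' @export
print.drink_constants <- function(x, ...) {
  cat("<drink_constants>\n")
  print(unlist(x))
  invisible(x)
}

#' @rdname tidy.drink_params
#' @export
tidy.drink_constants <- function(x, ...) {
  tibble::tibble(constant = names(x), value = unname(unlist(x)))
}

#' Basic reproduction number
#'
#' Threshold parameter of the model: the alcohol-free equilibrium attracts
#' when `R0 < 1` and a unique endemic equilibrium exists when `R0 > 1`.
#'
#' @inheritParams derived_constants
#' @return A single nonnegative number.
#' @examples
#' reproduction_number(table1_parameters())
#' @export
reproduction_number <- function(params) {
  derived_constants(params)$R0
}

#' @keywords internal
as_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, COMPARTMENTS])
  if (!is.null(names(state)) && all(COMPARTMENTS %in% names(state))) {
    state <- state[COMPARTMENTS]
  }
  if (length(state) != 7L || !all(is.finite(state))) {
    rlang::abort("state must be 7 finite compartment values (P, M, H, T, V, A, Q)",
                 class = "fracdrink_invalid_state")
  }
  stats::setNames(as.numeric(state), COMPARTMENTS)
}

#' Force of infection
#'
#' Per-capita rate at which potential drinkers take up moderate drinking,
#' \eqn{\lambda = (\beta_1 M + \beta_2 H) / N}, evaluated with the live total
#' population \eqn{N = P+M+H+T+V+A+Q}.
#'
#' @param state Compartment values: a named numeric vector or one-row data
#'   frame with entries `P, M, H, T, V, A, Q`.
#' @inheritParams derived_constants
#' @return A nonnegative rate.
#' @export
force_of_infection <- function(state, params) {
  s <- as_state(state)
  N <- sum(s)
  if (N <= 0) {
    rlang::abort("total population must be positive to evaluate the force of infection",
                 class = "fracdrink_degenerate_population")
  }
  (params$beta1 * s[["M"]] + params$beta2 * s[["H"]]) / N
}

#' Model vector field
#'
#' Right-hand side of the seven-compartment system, in the fixed order
#' (P, M, H, T, V, A, Q). The components sum to
#' `Lambda - nu*N - delta1*H - delta2*T - delta3*V - delta4*A`.
#'
#' @param t Time (the field is autonomous; `t` is accepted for the solver
#'   contract).
#' @inheritParams force_of_infection
#' @return Named numeric vector of the seven rates of change.
#' @export
drink_rhs <- function(t, state, params) {
  s <- as_state(state)
  lambda <- force_of_infection(s, params)
  p <- params
  q1 <- p$psi + p$nu
  q2 <- p$nu + p$theta1 + p$theta2 + p$theta3 + p$delta1 + p$phi
  q3 <- p$nu + p$delta2 + p$gamma1
  q4 <- p$nu + p$delta3 + p$gamma2
  q5 <- p$nu + p$delta4 + p$gamma3
  c(
    P = p$Lambda - (lambda + p$nu) * s[["P"]],
    M = lambda * s[["P"]] - q1 * s[["M"]],
    H = p$psi * s[["M"]] - q2 * s[["H"]],
    T = p$phi * s[["H"]] - q3 * s[["T"]],
    V = p$theta1 * s[["H"]] - q4 * s[["V"]],
    A = p$theta2 * s[["H"]] - q5 * s[["A"]],
    Q = p$theta3 * s[["H"]] + p$gamma1 * s[["T"]] + p$gamma2 * s[["V"]] +
      p$gamma3 * s[["A"]] - p$nu * s[["Q"]]
  )
}

#' Alcohol-free equilibrium
#'
#' The steady state with the whole population in the potential class:
#' `(Lambda/nu, 0, 0, 0, 0, 0, 0)`.
#'
#' @inheritParams derived_constants
#' @return Named numeric vector of compartment values.
#' @export
alcohol_free_equilibrium <- function(params) {
  p <- validate_drink_params(params)
  stats::setNames(c(p$Lambda / p$nu, 0, 0, 0, 0, 0, 0), COMPARTMENTS)
}

#' Endemic equilibrium
#'
#' The positive steady state, parameterised by the endemic force of infection
#' \eqn{\lambda^* = (R_0 - 1)/c_7}. It exists only when `R0 > 1`
#' (`R0 = 1` is treated as subcritical); otherwise `NULL` is returned.
#'
#' @inheritParams derived_constants
#' @return `NULL` if `R0 <= 1`; otherwise a list with `state` (named
#'   compartment vector) and `lambda_star`.
#' @examples
#' p <- table1_parameters()
#' endemic_equilibrium(p)            # NULL: R0 < 1
#' p$beta1 <- 0.6
#' endemic_equilibrium(p)$lambda_star
#' @export
endemic_equilibrium <- function(params) {
  p <- validate_drink_params(params)
  k <- derived_constants(p)
  if (k$R0 <= 1) return(NULL)
  lambda_star <- (k$R0 - 1) / k$c7
  P <- p$Lambda / (lambda_star + p$nu)
  state <- stats::setNames(c(
    P,
    k$c1 * lambda_star * P,
    k$c2 * lambda_star * P,
    k$c3 * lambda_star * P,
    k$c4 * lambda_star * P,
    k$c5 * lambda_star * P,
    k$c6 * lambda_star * P / p$nu
  ), COMPARTMENTS)
  list(state = state, lambda_star = lambda_star)
}

#' Both equilibria as a tibble
#'
#' @inheritParams derived_constants
#' @return A tibble with one row per existing equilibrium, columns
#'   `equilibrium` ("AFE"/"EE"), the seven compartments, and `lambda_star`
#'   (`NA` for the AFE).
#' @export
equilibria <- function(params) {
  afe <- alcohol_free_equilibrium(params)
  out <- tibble::as_tibble(as.list(afe))
  out <- dplyr::mutate(out, equilibrium = "AFE", lambda_star = NA_real_,
                       .before = 1)
  ee <- endemic_equilibrium(params)
  if (!is.null(ee)) {
    row <- tibble::as_tibble(as.list(ee$state))
    row <- dplyr::mutate(row, equilibrium = "EE", lambda_star = ee$lambda_star,
                         .before = 1)
    out <- dplyr::bind_rows(out, row)
  }
  dplyr::relocate(out, "lambda_star", .after = dplyr::last_col())
}

#' Check a trajectory against the feasible region
#'
#' The feasible region is the set of nonnegative states whose total
#' population does not exceed `Lambda/nu`; it is positively invariant under
#' the model flow. The check reports the most negative compartment value seen
#' and the worst excess of `N(t)` over `max(N(0), Lambda/nu)`.
#'
#' @param traj A trajectory tibble with columns `t, P, M, H, T, V, A, Q`
#'   (as returned by the solvers).
#' @inheritParams derived_constants
#' @param tol Absolute tolerance; defaults to `1e-6 * Lambda/nu`.
#' @return A one-row tibble with `min_compartment`, `max_n_excess`, `pass`.
#' @export
feasibility_check <- function(traj, params, tol = 1e-6 * params$Lambda / params$nu) {
  stopifnot(nrow(traj) >= 1L)
  X <- as.matrix(traj[, COMPARTMENTS])
  N <- rowSums(X)
  ceiling_N <- max(N[1L], params$Lambda / params$nu)
  min_comp <- min(X)
  max_excess <- max(N - ceiling_N)
  tibble::tibble(
    min_compartment = min_comp,
    max_n_excess = max_excess,
    tol = tol,
    pass = (min_comp >= -tol) && (max_excess <= tol)
  )
}
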