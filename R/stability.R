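#' Global Lipschitz constant of the model vector field
#'
#' On the feasible region the seven component fields are Lipschitz in their
#' own compartment with coefficients
#' `(beta1* + beta2* + nu, q1, q2, q3, q4, q5, nu)`, where `beta1*`, `beta2*`
#' bound the force-of-infection ratios; the global constant is their maximum.
#'
#' @inheritParams derived_constants
#' @param beta1_star,beta2_star Upper bounds on the contact-rate terms;
#'   default to the rates themselves (valid since `M/N`, `H/N` are at most 1
#'   in the feasible region).
#' @return The scalar Lipschitz constant.
#' @examples
#' lipschitz_constant(table1_parameters())
#' @export
lipschitz_constant <- function(params, beta1_star = params$beta1,
                               beta2_star = params$beta2) {
  p <- validate_drink_params(params)
  k <- derived_constants(p)
  max(beta1_star + beta2_star + p$nu, k$q1, k$q2, k$q3, k$q4, k$q5, p$nu)
}

#' Ulam-Hyers stability constants
#'
#' Computes `Delta3 = T^vartheta / Gamma(vartheta + 1)`, the per-compartment
#' contraction coefficients `Theta_i` (the Lipschitz coefficients of the
#' component fields, in compartment order:
#' `beta1*Delta1 + beta2*Delta2 + nu, q1, q2, q3, q4, q5, nu`), and, wherever
#' `Delta3 * Theta_i < 1`, the stability constants
#' `D_wi = Delta3 / (1 - Delta3 * Theta_i)`: every approximate solution with
#' residual at most `delta` then lies within `D_wi * delta` of the exact one.
#' The model is certified Ulam-Hyers stable on `[0, T]` when all seven
#' compartments are certified. The `Theta` assignment is a compartment-aligned
#' reconstruction from the componentwise Lipschitz bounds.
#'
#' Also reports the Picard contraction margin `eta * T^vartheta /
#' Gamma(vartheta + 1)` built from [lipschitz_constant()]; a margin below 1
#' certifies existence and uniqueness on the horizon by contraction.
#'
#' @inheritParams derived_constants
#' @param vartheta Fractional order in (0, 1].
#' @param t_end Horizon T (> 0).
#' @param Delta1,Delta2 Bounds on `M/N` and `H/N`, in (0, 1]; both ratios are
#'   at most 1 in the feasible region, hence the defaults.
#' @return A `drink_certificate` object; `tidy()` returns the
#'   per-compartment table.
#' @examples
#' cert <- uh_constants(table1_parameters(), vartheta = 1, t_end = 1)
#' tidy(cert)
#' @export
uh_constants <- function(params, vartheta, t_end, Delta1 = 1, Delta2 = 1) {
  stopifnot(vartheta > 0, vartheta <= 1,
            Delta1 > 0, Delta1 <= 1, Delta2 > 0, Delta2 <= 1)
  if (t_end <= 0) {
    rlang::abort("t_end must be positive", class = "fracdrink_domain_error")
  }
  p <- validate_drink_params(params)
  k <- derived_constants(p)
  Delta3 <- t_end^vartheta / exp(lgamma(vartheta + 1))
  Theta <- stats::setNames(
    c(p$beta1 * Delta1 + p$beta2 * Delta2 + p$nu,
      k$q1, k$q2, k$q3, k$q4, k$q5, p$nu),
    COMPARTMENTS
  )
  certified <- Delta3 * Theta < 1
  D_w <- ifelse(certified, Delta3 / (1 - Delta3 * Theta), NA_real_)
  eta <- lipschitz_constant(p)
  structure(
    list(
      vartheta = vartheta, t_end = t_end,
      Delta1 = Delta1, Delta2 = Delta2, Delta3 = Delta3,
      Theta = Theta, D_w = stats::setNames(D_w, COMPARTMENTS),
      certified = certified,
      uh_stable = all(certified),
      eta = eta,
      contraction_margin = eta * Delta3
    ),
    class = "drink_certificate"
  )
}

#' @export
print.drink_certificate <- function(x, ...) {
  cat(sprintf(
    "<drink_certificate> vartheta=%g T=%g Delta3=%.6g eta=%.6g margin=%.6g\n",
    x$vartheta, x$t_end, x$Delta3, x$eta, x$contraction_margin))
  cat(sprintf("Ulam-Hyers stable on [0, T]: %s (%d/7 compartments certified)\n",
              x$uh_stable, sum(x$certified)))
  invisible(x)
}

#' @rdname uh_constants
#' @param x A `drink_certificate`.
#' @param ... Unused.
#' @export
tidy.drink_certificate <- function(x, ...) {
  tibble::tibble(
    compartment = COMPARTMENTS,
    Theta = unname(x$Theta),
    Delta3_Theta = unname(x$Delta3 * x$Theta),
    certified = unname(x$certified),
    D_w = unname(x$D_w)
  )
}

#' @rdname uh_constants
#' @export
glance.drink_certificate <- function(x, ...) {
  tibble::tibble(
    vartheta = x$vartheta, t_end = x$t_end, Delta3 = x$Delta3,
    eta = x$eta, contraction_margin = x$contraction_margin,
    n_certified = sum(x$certified), uh_stable = x$uh_stable
  )
}

#' Picard existence and contraction margins for the fractal-fractional model
#'
#' For the power-law fractal-fractional initial-value problem on `[0, a]`,
#' the fixed-point operator maps the ball of radius `c` into itself when the
#' field bound `K` stays below
#' \eqn{\bar K = c\,\Gamma(\vartheta)/(\zeta a^{\zeta+\vartheta-1}B(\zeta,\vartheta))}
#' and contracts when the Lipschitz bound `L` stays below
#' \eqn{\bar L = \Gamma(\vartheta)/(\zeta a^{\zeta+\vartheta-1}B(\vartheta,\zeta))},
#' with `B` the Euler Beta function.
#'
#' @param vartheta,zeta Fractional and fractal orders in (0, 1].
#' @param a Horizon (> 0).
#' @param K Sup-norm bound on the field.
#' @param L Lipschitz bound on the field.
#' @param c Radius of the invariant ball (default 1).
#' @return A one-row tibble with the Beta value, both thresholds, the ratios
#'   `K/K_bar` and `L/L_bar`, and `certified` (both ratios below 1).
#' @examples
#' picard_existence_margin(1, 1, a = 1, K = 0.5, L = 0.5)
#' @export
picard_existence_margin <- function(vartheta, zeta, a, K, L, c = 1) {
  stopifnot(vartheta > 0, vartheta <= 1, zeta > 0, zeta <= 1, a > 0,
            K >= 0, L >= 0, c > 0)
  B <- beta(vartheta, zeta)
  denom <- zeta * a^(zeta + vartheta - 1) * B
  K_bar <- c * gamma(vartheta) / denom
  L_bar <- gamma(vartheta) / denom
  tibble::tibble(
    vartheta = vartheta, zeta = zeta, a = a, c = c,
    beta_value = B,
    K_bar = K_bar, L_bar = L_bar,
    ratio_K = K / K_bar, ratio_L = L / L_bar,
    certified = (K / K_bar < 1) && (L / L_bar < 1)
  )
}
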