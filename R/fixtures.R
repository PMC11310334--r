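#' Specification for synthetic model inputs
#'
#' Bundles the knobs of the synthetic-data generators: initial-condition
#' total and split, relative parameter jitter, observation noise, and the
#' seed that makes every generator deterministic.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @param N0 Initial total population; `NULL` means the demographic ceiling
#'   `Lambda/nu` of the parameter set in use.
#' @param ic_weights Seven nonnegative fractions summing to 1, the split of
#'   `N0` over (P, M, H, T, V, A, Q).
#' @param jitter Relative half-width for parameter perturbation draws.
#' @param sigma Standard deviation of the multiplicative log-normal
#'   observation noise.
#' @param obs_times Observation times (must be grid points of the trajectory
#'   being observed); `NULL` means every grid point.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, N0 = NULL,
                         ic_weights = c(0.50, 0.20, 0.15, 0.05, 0.05, 0.03, 0.02),
                         jitter = 0.2, sigma = 0.01, obs_times = NULL) {
  stopifnot(length(ic_weights) == 7L, all(ic_weights >= 0),
            abs(sum(ic_weights) - 1) <= 1e-12,
            jitter >= 0, sigma >= 0)
  structure(
    list(seed = as.integer(seed), N0 = N0,
         ic_weights = stats::setNames(ic_weights, COMPARTMENTS),
         jitter = jitter, sigma = sigma, obs_times = obs_times),
    class = "fixture_spec"
  )
}

#' Feasible initial conditions
#'
#' Splits a total population `N0` over the seven compartments by the spec's
#' weights. By default `N0 = Lambda/nu`, the boundary of the feasible region,
#' so the invariance bound is exercised from the start. Requests with
#' `N0 > Lambda/nu` are rejected when `feasible = TRUE`.
#'
#' @param spec A [fixture_spec()].
#' @inheritParams derived_constants
#' @param feasible Enforce `N0 <= Lambda/nu`.
#' @return Named compartment vector.
#' @examples
#' initial_conditions()
#' @export
initial_conditions <- function(spec = fixture_spec(),
                               params = table1_parameters(),
                               feasible = TRUE) {
  p <- validate_drink_params(params)
  N0 <- spec$N0 %||% (p$Lambda / p$nu)
  if (feasible && N0 > p$Lambda / p$nu + 1e-12) {
    rlang::abort("requested N0 exceeds the feasible ceiling Lambda/nu",
                 class = "fracdrink_infeasible_ic")
  }
  N0 * spec$ic_weights
}

#' Perturbed parameter draws around a base calibration
#'
#' Each rate is drawn independently and uniformly in
#' `[p(1 - jitter), p(1 + jitter)]`; `Lambda` and `nu` are floored at 1e-6 so
#' the demographic ceiling stays defined. Draws are reproducible from the
#' spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param n Number of draws.
#' @param base Base `drink_params`.
#' @return A list of `n` validated `drink_params` objects.
#' @export
perturbed_parameters <- function(spec = fixture_spec(), n = 1L,
                                 base = table1_parameters()) {
  stopifnot(n >= 1)
  b <- unlist(unclass(validate_drink_params(base)))
  w <- spec$jitter
  withr::with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      vals <- b * stats::runif(length(b), 1 - w, 1 + w)
      vals[["Lambda"]] <- max(vals[["Lambda"]], 1e-6)
      vals[["nu"]] <- max(vals[["nu"]], 1e-6)
      validate_drink_params(as.list(vals))
    })
  })
}

#' Noisy observations of a trajectory
#'
#' Applies independent multiplicative log-normal noise,
#' `observed = true * exp(eps)` with `eps ~ Normal(0, sigma^2)`, to every
#' state column at the spec's observation times. Positivity of counts is
#' preserved by construction; `sigma = 0` returns the truth.
#'
#' @param traj A trajectory tibble (column `t` plus state columns).
#' @param spec A [fixture_spec()].
#' @return A tibble with the same columns, restricted to the observation
#'   times.
#' @export
noisy_observations <- function(traj, spec = fixture_spec()) {
  df <- tibble::as_tibble(traj)
  if (!is.null(spec$obs_times)) {
    keep <- df$t %in% spec$obs_times
    if (sum(keep) != length(spec$obs_times)) {
      rlang::abort("obs_times must be a subset of the trajectory grid",
                   class = "fracdrink_invalid_state")
    }
    df <- df[keep, , drop = FALSE]
  }
  state_cols <- setdiff(names(df), "t")
  X <- as.matrix(df[, state_cols])
  withr::with_seed(spec$seed, {
    eps <- matrix(stats::rnorm(length(X), 0, spec$sigma), nrow(X), ncol(X))
  })
  df[, state_cols] <- X * exp(eps)
  df
}
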