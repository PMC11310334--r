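#' Relative max-norm distance between a state and an equilibrium
#' @keywords internal
rel_distance <- function(state, eq) {
  max(abs(state - eq)) / max(abs(eq))
}

#' Build a scenario configuration
#'
#' A scenario is a parameter set, a grid of (fractional, fractal) orders, a
#' set of contact-rate multipliers, a time grid, and an initial condition.
#' One solver run is performed per (order x multiplier) cell.
#'
#' @inheritParams derived_constants
#' @param name Scenario label.
#' @param vartheta,zeta Vectors of fractional and fractal orders; the order
#'   grid is their crossing unless `orders` is supplied.
#' @param orders Optional data frame with columns `vartheta`, `zeta` giving
#'   explicit order pairs (overrides `vartheta`/`zeta`).
#' @param multipliers Contact-rate multipliers in (0, 1], applied to the
#'   rates named in `apply_to`.
#' @param apply_to Which contact rates the multipliers scale.
#' @param t_end,n_steps Time grid (`n_steps >= 2`).
#' @param ic Initial condition; defaults to [initial_conditions()] under the
#'   scenario parameters.
#' @param solver One of "fractal_fractional", "caputo", "classical".
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(name = "scenario",
                            params = table1_parameters(),
                            vartheta = c(0.85, 0.90, 0.95, 1),
                            zeta = 1,
                            orders = NULL,
                            multipliers = 1,
                            apply_to = c("beta1", "beta2"),
                            t_end = 400, n_steps = 4000,
                            ic = NULL,
                            solver = c("fractal_fractional", "caputo", "classical")) {
  solver <- match.arg(solver)
  if (is.null(orders)) {
    orders <- tidyr::expand_grid(vartheta = vartheta, zeta = zeta)
  }
  orders <- tibble::as_tibble(orders)
  stopifnot(nrow(orders) >= 1L,
            all(orders$vartheta > 0 & orders$vartheta <= 1),
            all(orders$zeta > 0 & orders$zeta <= 1),
            all(multipliers > 0 & multipliers <= 1),
            all(apply_to %in% c("beta1", "beta2")))
  if (t_end <= 0 || n_steps < 2) {
    rlang::abort("scenario requires t_end > 0 and n_steps >= 2",
                 class = "fracdrink_invalid_config")
  }
  params <- validate_drink_params(params)
  structure(
    list(name = name, params = params, orders = orders,
         multipliers = multipliers, apply_to = apply_to,
         t_end = t_end, n_steps = as.integer(n_steps),
         ic = ic %||% initial_conditions(fixture_spec(), params),
         solver = solver),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' Recognised keys: `name`, `params` (flat rate map, or absent for the
#' packaged baseline), `vartheta`, `zeta` (lists), `orders` (list of
#' `{vartheta, zeta}` pairs), `multipliers`, `apply_to`, `t_end`, `n_steps`,
#' `ic_weights`, `N0`, `solver`.
#'
#' @param path YAML file.
#' @return A `scenario_config` object.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- if (is.null(y$params)) table1_parameters() else
    validate_drink_params(lapply(y$params, as.numeric))
  spec <- fixture_spec(
    N0 = y$N0,
    ic_weights = if (is.null(y$ic_weights)) {
      c(0.50, 0.20, 0.15, 0.05, 0.05, 0.03, 0.02)
    } else as.numeric(y$ic_weights)
  )
  orders <- if (!is.null(y$orders)) {
    dplyr::bind_rows(lapply(y$orders, tibble::as_tibble))
  } else NULL
  scenario_config(
    name = y$name %||% tools::file_path_sans_ext(basename(path)),
    params = params,
    vartheta = as.numeric(y$vartheta %||% c(0.85, 0.90, 0.95, 1)),
    zeta = as.numeric(y$zeta %||% 1),
    orders = orders,
    multipliers = as.numeric(y$multipliers %||% 1),
    apply_to = as.character(y$apply_to %||% c("beta1", "beta2")),
    t_end = as.numeric(y$t_end %||% 400),
    n_steps = as.integer(y$n_steps %||% 4000),
    ic = initial_conditions(spec, params),
    solver = y$solver %||% "fractal_fractional"
  )
}

#' @keywords internal
solve_cell <- function(params, ic, vartheta, zeta, t_end, n_steps, solver) {
  switch(solver,
    caputo = solve_caputo(params, ic, vartheta, t_end, n_steps),
    classical = solve_classical(params, ic, t_end, n_steps),
    fractal_fractional = solve_fractal_fractional(params, ic, vartheta, zeta,
                                                  t_end, n_steps)
  )
}

#' @keywords internal
classify_terminal <- function(traj, params, tol = 0.01, band = 0.05) {
  afe <- alcohol_free_equilibrium(params)
  ee <- endemic_equilibrium(params)
  X <- as.matrix(traj[, COMPARTMENTS])
  terminal <- X[nrow(X), ]
  cands <- list(AFE = afe)
  if (!is.null(ee)) cands$EE <- ee$state
  dists <- vapply(cands, function(e) rel_distance(terminal, e), numeric(1))
  best <- names(dists)[which.min(dists)]
  attractor <- if (min(dists) <= tol) best else "undecided"
  # first time from which the path stays within `band` of the attractor
  time_to_band <- NA_real_
  if (attractor != "undecided") {
    eq <- cands[[best]]
    scale <- max(abs(eq))
    d_t <- apply(abs(X - matrix(eq, nrow(X), 7, byrow = TRUE)), 1, max) / scale
    inside_forever <- rev(cummax(rev(d_t))) <= band
    if (any(inside_forever)) time_to_band <- traj$t[which(inside_forever)[1L]]
  }
  list(attractor = attractor, terminal_residual = unname(min(dists)),
       time_to_band = time_to_band)
}

#' Run a simulation scenario over its order-by-multiplier grid
#'
#' Solves the model once per cell, classifies the attractor reached (the
#' equilibrium whose relative max-norm distance at the horizon is at most
#' `tol`, else "undecided"), and reports the terminal residual and the time
#' from which the path stays within a 5% band of the attractor.
#'
#' @param config A [scenario_config()].
#' @param tol Classification tolerance (relative max-norm at the horizon).
#' @param out_dir If non-`NULL`, trajectories (CSV + JSON sidecar) and the
#'   summary CSV are written there.
#' @return A tibble with one row per cell: `scenario`, `vartheta`, `zeta`,
#'   `multiplier`, `R0`, `attractor`, `terminal_residual`, `time_to_band`,
#'   and a `trajectory` list-column.
#' @examples
#' cfg <- scenario_config(vartheta = c(0.9, 1), t_end = 120, n_steps = 600)
#' run_scenario(cfg)[, 1:7]
#' @export
run_scenario <- function(config, tol = 0.01, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- tidyr::expand_grid(config$orders, multiplier = config$multipliers)
  rows <- purrr::pmap(grid, function(vartheta, zeta, multiplier) {
    p <- config$params
    for (nm in config$apply_to) p[[nm]] <- p[[nm]] * multiplier
    p <- validate_drink_params(p)
    traj <- solve_cell(p, config$ic, vartheta, zeta,
                       config$t_end, config$n_steps, config$solver)
    cls <- classify_terminal(traj, p, tol = tol)
    tibble::tibble(
      scenario = config$name, vartheta = vartheta, zeta = zeta,
      multiplier = multiplier, R0 = reproduction_number(p),
      attractor = cls$attractor, terminal_residual = cls$terminal_residual,
      time_to_band = cls$time_to_band, trajectory = list(traj)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::pwalk(out, function(scenario, vartheta, zeta, multiplier, R0,
                               attractor, terminal_residual, time_to_band,
                               trajectory) {
      fn <- sprintf("%s_v%0.2f_z%0.2f_m%0.2f.csv", scenario, vartheta, zeta,
                    multiplier)
      write_trajectory(trajectory, file.path(out_dir, fn))
    })
    utils::write.csv(dplyr::select(out, -"trajectory"),
                     file.path(out_dir, paste0(config$name, "_summary.csv")),
                     row.names = FALSE)
  }
  out
}

#' Cumulative-burden sweep over contact-rate reductions
#'
#' Scales the contact rates by each multiplier, solves the model for each
#' fractional order, and reports the cumulative burden — the time-integral of
#' the compartment over the horizon, by the trapezoid rule on the solver grid
#' — for the moderate, heavy, violent and accident classes.
#'
#' @inheritParams derived_constants
#' @param multipliers Contact-rate multipliers (1 = baseline).
#' @param vartheta Fractional orders to sweep.
#' @param zeta Fractal order (single value).
#' @param t_end,n_steps Time grid.
#' @param ic Initial condition.
#' @param apply_to Which contact rates the multipliers scale.
#' @param compartments Burden compartments.
#' @return A long tibble: `multiplier`, `vartheta`, `zeta`, `R0`,
#'   `compartment`, `burden`.
#' @export
contact_rate_sweep <- function(params = table1_parameters(),
                               multipliers = c(1, 0.75, 0.5, 0.25),
                               vartheta = c(1, 0.88), zeta = 1,
                               t_end = 100, n_steps = 1000,
                               ic = initial_conditions(fixture_spec(), params),
                               apply_to = c("beta1", "beta2"),
                               compartments = c("M", "H", "V", "A")) {
  grid <- tidyr::expand_grid(multiplier = multipliers, vartheta = vartheta)
  rows <- purrr::pmap(grid, function(multiplier, vartheta) {
    p <- params
    for (nm in apply_to) p[[nm]] <- p[[nm]] * multiplier
    p <- validate_drink_params(p)
    traj <- solve_fractal_fractional(p, ic, vartheta, zeta, t_end, n_steps)
    h <- attr(traj, "h")
    burden <- vapply(compartments, function(cc) {
      y <- traj[[cc]]
      h * (sum(y) - (y[1L] + y[length(y)]) / 2)
    }, numeric(1))
    tibble::tibble(
      multiplier = multiplier, vartheta = vartheta, zeta = zeta,
      R0 = reproduction_number(p),
      compartment = compartments, burden = unname(burden)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drink_sweep", class(out))
  out
}

#' Plot a contact-rate sweep
#'
#' @param object The tibble returned by [contact_rate_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drink_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$multiplier, y = .data$burden,
                               colour = factor(.data$vartheta))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "contact-rate multiplier", y = "cumulative burden",
                  colour = "fractional order")
}
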