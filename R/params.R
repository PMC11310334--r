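#' @keywords internal
PARAM_NAMES <- c(
  "Lambda", "nu", "beta1", "beta2", "psi", "phi",
  "theta1", "theta2", "theta3",
  "gamma1", "gamma2", "gamma3",
  "delta1", "delta2", "delta3", "delta4"
)

#' @keywords internal
COMPARTMENTS <- c("P", "M", "H", "T", "V", "A", "Q")

#' Construct a validated parameter set for the alcohol-addiction model
#'
#' The model tracks seven compartments: potential drinkers (P), moderate
#' drinkers (M), heavy drinkers (H), drinkers under treatment (T), heavy
#' drinkers turned violent (V), heavy drinkers causing road accidents (A),
#' and quitters/recovered (Q). All rates are per unit time.
#'
#' @param Lambda Recruitment rate into the potential-drinker class (persons/time).
#' @param nu Natural death rate (must be positive: the demographic ceiling
#'   `Lambda/nu` and the residence time `1/(psi+nu)` must be defined).
#' @param beta1 Contact rate of potential with moderate drinkers.
#' @param beta2 Contact rate of potential with heavy drinkers.
#' @param psi Progression rate from moderate to heavy drinking.
#' @param phi Rate at which heavy drinkers enter treatment.
#' @param theta1 Rate at which heavy drinkers become violent.
#' @param theta2 Rate at which heavy drinkers cause road accidents.
#' @param theta3 Quitting rate of heavy drinkers.
#' @param gamma1,gamma2,gamma3 Recovery rates from the T, V and A classes.
#' @param delta1,delta2,delta3,delta4 Induced death rates in H, T, V and A.
#'
#' @return A `drink_params` object: a named list of the 16 rates.
#' @seealso [table1_parameters()] for the packaged baseline calibration.
#' @examples
#' p <- table1_parameters()
#' reproduction_number(p)
#' @export
drink_params <- function(Lambda, nu, beta1, beta2, psi, phi,
                         theta1, theta2, theta3,
                         gamma1, gamma2, gamma3,
                         delta1, delta2, delta3, delta4) {
  p <- list(
    Lambda = Lambda, nu = nu, beta1 = beta1, beta2 = beta2,
    psi = psi, phi = phi,
    theta1 = theta1, theta2 = theta2, theta3 = theta3,
    gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
    delta1 = delta1, delta2 = delta2, delta3 = delta3, delta4 = delta4
  )
  validate_drink_params(p)
}

#' @keywords internal
validate_drink_params <- function(p) {
  vals <- unlist(p[PARAM_NAMES])
  if (length(vals) != 16L || anyNA(vals) || !all(is.finite(vals))) {
    rlang::abort("all 16 model parameters must be finite numbers",
                 class = "fracdrink_invalid_parameter")
  }
  if (any(vals < 0)) {
    bad <- PARAM_NAMES[vals < 0]
    rlang::abort(paste0("negative rate(s): ", paste(bad, collapse = ", ")),
                 class = "fracdrink_invalid_parameter")
  }
  if (p$nu <= 0 || p$Lambda <= 0) {
    rlang::abort("Lambda and nu must be strictly positive",
                 class = "fracdrink_invalid_parameter")
  }
  structure(p[PARAM_NAMES], class = "drink_params")
}

#' Baseline parameter calibration of the alcohol model
#'
#' Returns the packaged baseline rates. `gamma1` is stored as the exact
#' quotient `0.0020 / 52` (a weekly recovery fraction expressed per year).
#' With these values the basic reproduction number is about 0.8705, so the
#' alcohol-free equilibrium is the attractor.
#'
#' @return A `drink_params` object.
#' @examples
#' table1_parameters()$Lambda
#' @export
table1_parameters <- function() {
  drink_params(
    Lambda = 159.5, nu = 0.1595,
    beta1 = 0.4, beta2 = 0.00001,
    psi = 0.3, phi = 0.70,
    theta1 = 0.03, theta2 = 0.02, theta3 = 0.3,
    gamma1 = 0.0020 / 52, gamma2 = 0.001, gamma3 = 0.001,
    delta1 = 0.035, delta2 = 0.30, delta3 = 0.002, delta4 = 0.001
  )
}

#' @export
print.drink_params <- function(x, ...) {
  cat("<drink_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.data.frame.drink_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Tidy a parameter set into a two-column tibble
#'
#' @param x A `drink_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.drink_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unname(unlist(x)))
}

#' Read or write a parameter set as a flat YAML or JSON file
#'
#' Keys are the 16 rate names (`Lambda`, `nu`, `beta1`, ...). The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params A `drink_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a validated `drink_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "drink_params"))
  vals <- lapply(unclass(params), as.numeric)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 17L)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  missing <- setdiff(PARAM_NAMES, names(vals))
  if (length(missing)) {
    rlang::abort(paste0("parameter file is missing: ", paste(missing, collapse = ", ")),
                 class = "fracdrink_invalid_parameter")
  }
  validate_drink_params(lapply(vals[PARAM_NAMES], as.numeric))
}
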