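test_that("the Lipschitz constant is the worst componentwise coefficient", {
  k <- derived_constants(tbl1)
  expect_equal(lipschitz_constant(tbl1), k$q2)
  expect_equal(lipschitz_constant(tbl1), 1.2445)
  # degenerate calibration where every coefficient collapses to nu
  p <- drink_params(Lambda = 1, nu = 1, beta1 = 0, beta2 = 0, psi = 0,
                    phi = 0, theta1 = 0, theta2 = 0, theta3 = 0,
                    gamma1 = 0, gamma2 = 0, gamma3 = 0,
                    delta1 = 0, delta2 = 0, delta3 = 0, delta4 = 0)
  expect_equal(lipschitz_constant(p), 1)
})

test_that("the Lipschitz constant is nondecreasing in every rate it involves", {
  draws <- perturbed_parameters(fixture_spec(seed = 5, jitter = 0.3), 20)
  rates <- c("beta1", "beta2", "nu", "psi", "phi", "theta1", "theta2",
             "theta3", "gamma1", "gamma2", "gamma3",
             "delta1", "delta2", "delta3", "delta4")
  for (p in draws) {
    eta <- lipschitz_constant(p)
    for (nm in rates) {
      up <- p; up[[nm]] <- up[[nm]] + 1e-3
      expect_gte(lipschitz_constant(up), eta)
    }
  }
})

test_that("stability constants reproduce hand-computed certificate values", {
  expect_equal(uh_constants(tbl1, 1, 1)$Delta3, 1)  # 1 / Gamma(2)
  cert <- uh_constants(tbl1, 1, 1, Delta1 = 1, Delta2 = 1)
  expect_equal(unname(cert$Theta[["P"]]), 0.55951)
  expect_equal(unname(cert$D_w[["P"]]), 1 / (1 - 0.55951))
  # the heavy-drinker coefficient q2 = 1.2445 >= 1 cannot be certified at T = 1
  expect_false(cert$certified[["H"]])
  expect_true(is.na(cert$D_w[["H"]]))
  expect_false(cert$uh_stable)
  expect_error(uh_constants(tbl1, 0.9, 0), class = "fracdrink_domain_error")
})

test_that("stability constants approach their limits in Theta and Delta3", {
  # Theta -> 0 pins D_w at Delta3
  p <- tbl1; p$beta1 <- 0; p$beta2 <- 0; p$nu <- 1e-8; p$Lambda <- 1e-6
  cert <- uh_constants(p, 0.9, 1)
  expect_equal(unname(cert$D_w[["P"]]), cert$Delta3, tolerance = 1e-6)
  # Delta3 * Theta -> 1 from below sends D_w to infinity
  crit_T <- (0.99999 / (1.2445 / gamma(2)))  # just under the certification edge
  d <- vapply(c(0.9, 0.99, 0.99999), function(f) {
    unname(uh_constants(tbl1, 1, f * crit_T / 0.99999)$D_w[["H"]])
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_gt(d[3], 1e4)
})

test_that("Picard margins reproduce their closed-form thresholds", {
  m <- picard_existence_margin(1, 1, a = 1, K = 1, L = 1)
  expect_equal(m$beta_value, 1)
  expect_equal(m$K_bar, 1)
  expect_equal(m$L_bar, 1)
  expect_false(m$certified)
  m2 <- picard_existence_margin(1, 1, a = 0.5, K = 0, L = 1)
  expect_equal(m2$ratio_L, 0.5)
  expect_true(m2$certified)
})

test_that("Picard thresholds tighten monotonically with the horizon", {
  as <- c(0.25, 0.5, 1, 2, 4)
  th <- vapply(as, function(a) {
    picard_existence_margin(0.8, 0.9, a = a, K = 0, L = 0)$L_bar
  }, numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("the Beta value agrees between the gamma route and quadrature", {
  for (pair in list(c(0.5, 0.5), c(0.8, 0.9), c(1, 0.6))) {
    v <- pair[1]; z <- pair[2]
    num <- stats::integrate(function(x) x^(v - 1) * (1 - x)^(z - 1),
                            0, 1, rel.tol = 1e-12)$value
    expect_equal(picard_existence_margin(v, z, 1, 0, 0)$beta_value, num,
                 tolerance = 1e-10)
  }
})

test_that("certified horizons bound observed trajectory divergence", {
  v <- 0.9; T_h <- 0.7
  cert <- uh_constants(tbl1, v, T_h)
  expect_true(cert$uh_stable)
  D_max <- max(cert$D_w)
  base <- solve_caputo(tbl1, ic_default, v, t_end = T_h, n_steps = 100)
  set.seed(99)
  for (i in 1:50) {
    eps <- stats::runif(7, -0.5, 0.5)
    ic2 <- ic_default + eps
    pert <- solve_caputo(tbl1, ic2, v, t_end = T_h, n_steps = 100)
    div <- max(abs(traj_matrix(base) - traj_matrix(pert)))
    expect_lte(div, D_max * max(abs(eps)) * 1.1)
  }
})
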