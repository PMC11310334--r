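test_that("force of infection follows its closed form and edge cases", {
  p <- tbl1
  s <- c(P = 650, M = 200, H = 150, T = 0, V = 0, A = 0, Q = 0)
  expect_equal(force_of_infection(s, p), (0.4 * 200 + 0.00001 * 150) / 1000)
  expect_identical(force_of_infection(c(P = 10, M = 0, H = 0, T = 0, V = 0, A = 0, Q = 0), p), 0)
  expect_equal(force_of_infection(c(P = 0, M = 5, H = 0, T = 0, V = 0, A = 0, Q = 0), p), p$beta1)
  expect_error(force_of_infection(rep(0, 7), p),
               class = "fracdrink_degenerate_population")
})

test_that("vector-field components respect mass bookkeeping identically", {
  set.seed(42)
  for (i in 1:200) {
    s <- stats::runif(7, 0, 500)
    names(s) <- COMP
    r <- drink_rhs(0, s, tbl1)
    N <- sum(s)
    expected <- tbl1$Lambda - tbl1$nu * N - tbl1$delta1 * s[["H"]] -
      tbl1$delta2 * s[["T"]] - tbl1$delta3 * s[["V"]] - tbl1$delta4 * s[["A"]]
    expect_equal(sum(r), expected, tolerance = 1e-12)
  }
})

test_that("a lone heavy drinker feeds the treatment class at rate phi", {
  s <- c(P = 1, M = 0, H = 1, T = 0, V = 0, A = 0, Q = 0)
  r <- drink_rhs(0, s, tbl1)
  expect_equal(unname(r[["T"]]), 0.70)
})

test_that("the alcohol-free equilibrium is Lambda/nu on the potential axis", {
  afe <- alcohol_free_equilibrium(tbl1)
  expect_equal(unname(afe[["P"]]), 1000)
  expect_true(all(afe[-1] == 0))
  expect_lt(max(abs(drink_rhs(0, afe, tbl1))), 1e-12 * tbl1$Lambda)
  p <- tbl1; p$Lambda <- p$nu
  expect_equal(unname(alcohol_free_equilibrium(p)[["P"]]), 1)
})

test_that("endemic equilibrium exists exactly when R0 exceeds one", {
  expect_null(endemic_equilibrium(tbl1))  # R0 ~ 0.87 < 1
  k <- derived_constants(tbl1)
  crit <- tbl1
  crit$beta1 <- (k$q1 * k$q2 - tbl1$psi * tbl1$beta2) / k$q2  # R0 = 1 exactly
  expect_equal(reproduction_number(crit), 1)
  expect_null(endemic_equilibrium(crit))  # boundary treated as subcritical
  # just above the threshold the equilibrium detaches continuously from AFE
  crit$beta1 <- crit$beta1 * (1 + 1e-6)
  ee <- endemic_equilibrium(crit)
  expect_gt(ee$lambda_star, 0)
  expect_lt(ee$lambda_star, 1e-5)
})

test_that("endemic equilibrium zeroes the field and satisfies the
           force-of-infection identity", {
  p <- tbl1; p$beta1 <- 0.6
  ee <- endemic_equilibrium(p)
  expect_lt(max(abs(drink_rhs(0, ee$state, p))), 1e-9 * p$Lambda)
  expect_equal(ee$lambda_star, unname(force_of_infection(ee$state, p)),
               tolerance = 1e-12)
})

test_that("closed-form lambda* agrees with the bisection oracle on random
           supercritical parameter sets", {
  base <- tbl1; base$beta1 <- 0.6
  draws <- perturbed_parameters(fixture_spec(seed = 7, jitter = 0.2), 150, base)
  super <- Filter(function(p) reproduction_number(p) > 1, draws)
  expect_gte(length(super), 100)
  for (p in super[seq_len(100)]) {
    ee <- endemic_equilibrium(p)
    oracle <- bisect_lambda_star(p)
    expect_equal(ee$lambda_star, oracle, tolerance = 1e-8)
  }
})

test_that("equilibrium presence is threshold-consistent over random draws", {
  draws <- perturbed_parameters(fixture_spec(seed = 3, jitter = 0.6), 1000)
  for (p in draws) {
    ee <- endemic_equilibrium(p)
    if (reproduction_number(p) > 1) expect_false(is.null(ee))
    else expect_null(ee)
  }
})

test_that("equilibria() tabulates the AFE always and the EE when supercritical", {
  eq <- equilibria(tbl1)
  expect_equal(eq$equilibrium, "AFE")
  p <- tbl1; p$beta1 <- 0.6
  eq2 <- equilibria(p)
  expect_equal(eq2$equilibrium, c("AFE", "EE"))
  expect_true(is.na(eq2$lambda_star[1]) && eq2$lambda_star[2] > 0)
})

test_that("feasibility check passes invariant trajectories and flags
           injected violations", {
  traj <- solve_classical(tbl1, ic_default, t_end = 50, n_steps = 500)
  rep1 <- feasibility_check(traj, tbl1)
  expect_true(rep1$pass)
  # started on the boundary N(0) = Lambda/nu, the total never exceeds it
  expect_lte(rep1$max_n_excess, 1e-6 * tbl1$Lambda / tbl1$nu)
  bad <- traj
  bad$M[10] <- -5
  expect_false(feasibility_check(bad, tbl1)$pass)
})
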