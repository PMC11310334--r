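# Shared fixtures and independent oracles for the test suite.

tbl1 <- table1_parameters()
ic_default <- initial_conditions(fixture_spec(), tbl1)
COMP <- c("P", "M", "H", "T", "V", "A", "Q")

terminal_state <- function(traj) {
  unlist(traj[nrow(traj), COMP])
}

rel_dist <- function(state, eq) max(abs(state - eq)) / max(abs(eq))

traj_matrix <- function(traj) as.matrix(traj[, setdiff(names(traj), "t")])

# Independent equilibrium oracle: for a trial force of infection lambda, build
# the steady state directly from the balance equations (no c_i shortcuts), and
# bisect the fixed-point equation lambda = (beta1 M + beta2 H)/N.
steady_state_at_lambda <- function(lambda, p) {
  q1 <- p$psi + p$nu
  q2 <- p$nu + p$theta1 + p$theta2 + p$theta3 + p$delta1 + p$phi
  q3 <- p$nu + p$delta2 + p$gamma1
  q4 <- p$nu + p$delta3 + p$gamma2
  q5 <- p$nu + p$delta4 + p$gamma3
  P <- p$Lambda / (lambda + p$nu)
  M <- lambda * P / q1
  H <- p$psi * M / q2
  T <- p$phi * H / q3
  V <- p$theta1 * H / q4
  A <- p$theta2 * H / q5
  Q <- (p$theta3 * H + p$gamma1 * T + p$gamma2 * V + p$gamma3 * A) / p$nu
  c(P = P, M = M, H = H, T = T, V = V, A = A, Q = Q)
}

bisect_lambda_star <- function(p, upper = 10) {
  g <- function(lambda) {
    s <- steady_state_at_lambda(lambda, p)
    lambda - (p$beta1 * s[["M"]] + p$beta2 * s[["H"]]) / sum(s)
  }
  stats::uniroot(g, c(1e-12, upper), tol = 1e-14)$root
}
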