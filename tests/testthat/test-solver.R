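test_that("windkessel reaches the Ohmic steady state and decays with tau = R2 C", {
  # steady Q = 5 ml/s through R1 + R2 = 1.6e9 Pa s/m^3 gives 8 kPa
  R1 <- 2e8; R2 <- 1.4e9; C <- 1e-9
  a0 <- pi * 0.004^2
  beta <- 2e5
  q0 <- 5e-6
  out <- list(R1 = R1, R2 = R2, C = C, p_out = 0, Pc = 0)
  # drive with a constant end state carrying flow q0 until equilibrium
  dt <- 1e-4
  state <- list(A = a0, u = q0 / a0, beta = beta, A0 = a0)
  for (i in seq_len(200000)) {
    st <- windkessel_step(out, state, dt)
    out <- st$outlet
    # hold the upstream characteristic fixed at the target flow
    state$A <- st$A; state$u <- q0 / st$A
  }
  expect_equal(st$Q, q0, tolerance = 1e-3)
  expect_equal(st$P, q0 * (R1 + R2), tolerance = 5e-3)
  # flow shut off: stored pressure decays exponentially with tau = R2 C.
  # Hold the vessel end in equilibrium with the stored pressure (tube
  # pressure = Pc, zero velocity) so the interface flow is exactly zero
  # and the capacitor discharges through R2 alone.
  pc0 <- out$Pc
  tau <- R2 * C
  nstep <- round(2 * tau / dt)
  for (i in seq_len(nstep)) {
    a_eq <- a0 * (1 + out$Pc / beta)^2
    st <- windkessel_step(out, list(A = a_eq, u = 0, beta = beta, A0 = a0), dt)
    out <- st$outlet
  }
  expect_equal(out$Pc / pc0, exp(-2), tolerance = 0.01)
})

test_that("a very large compliance clamps the interface pressure to R1 Q + Pout", {
  R1 <- 2e8; R2 <- 1.4e9; C <- 1e-3   # enormous capacitor
  a0 <- pi * 0.004^2
  q0 <- 5e-6
  out <- list(R1 = R1, R2 = R2, C = C, p_out = 0, Pc = 0)
  st <- windkessel_step(out, list(A = a0, u = q0 / a0, beta = 2e5, A0 = a0), 1e-4)
  expect_equal(st$P, R1 * st$Q + 0, tolerance = 1e-6)
})

test_that("junction interface states satisfy all three coupling conditions", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    a0 <- stats::runif(k, 1e-6, 1e-4)
    beta <- stats::runif(k, 5e4, 5e5)
    a <- a0 * stats::runif(k, 0.95, 1.15)
    u <- stats::rnorm(k, 0.3, 0.4)
    r <- solve_junction(a, u, beta, a0)
    expect_lt(r$mass_residual_rel, 1e-10)
    expect_lt(max(r$char_residual), 1e-10)
    expect_lt(max(abs(r$total_pressure - r$total_pressure[1])) /
                max(abs(r$total_pressure[1]), 1), 1e-9)
  }
})

test_that("two identical vessels in series form a transparent interface", {
  a0 <- 1e-5; beta <- 1e5
  r <- solve_junction(c(1.08e-5, 1.08e-5), c(0.4, 0.4), c(beta, beta), c(a0, a0))
  expect_equal(r$A[1], r$A[2], tolerance = 1e-8)
  expect_equal(r$Q[1], r$Q[2], tolerance = 1e-8)
  expect_equal(r$A[1], 1.08e-5, tolerance = 1e-8)
})

test_that("a symmetric pentafurcation splits the parent flow five ways", {
  a0p <- 2e-5; a0c <- a0p / 5
  r <- solve_junction(c(a0p * 1.1, rep(a0c * 1.1, 5)),
                      c(0.5, rep(0.45, 5)),
                      c(1e5, rep(1.8e5, 5)),
                      c(a0p, rep(a0c, 5)))
  expect_equal(r$Q[2:6], rep(r$Q[1] / 5, 5), tolerance = 1e-10)
})

test_that("a symmetric bifurcation network splits flow exactly in half", {
  net <- bifurcation_net()
  res <- run_simulation(net, generate_inlet_waveform(8e-5),
                        numerics = numerics_config(max_cycles = 4,
                                                   convergence_tolerance = 1e-4))
  q1 <- res$Q["c1_mid", ]; q2 <- res$Q["c2_mid", ]
  expect_lt(max(abs(q1 - q2)) / max(abs(q1)), 1e-6)
})

test_that("identical inputs give bit-identical simulations", {
  net <- bifurcation_net()
  inlet <- generate_inlet_waveform(8e-5)
  r1 <- run_simulation(net, inlet)
  r2 <- run_simulation(net, inlet)
  expect_identical(r1$P, r2$P)
  expect_identical(r1$Q, r2$Q)
})

test_that("reported velocity equals flow over area pointwise", {
  net <- single_vessel_net()
  res <- run_simulation(net, generate_inlet_waveform(8e-5))
  expect_equal(res$u, res$Q / res$A, tolerance = 1e-14)
  expect_equal(ncol(res$P), numerics_config()$samples_per_cycle)
})

test_that("the as-printed friction variant runs and differs from the standard form", {
  net <- single_vessel_net()
  inlet <- constant_inflow(5e-5)
  ns <- numerics_config(max_cycles = 10, convergence_tolerance = 1e-4)
  np <- numerics_config(max_cycles = 10, convergence_tolerance = 1e-4,
                        friction_form = "as-printed")
  rs <- run_simulation(net, inlet, numerics = ns)
  rp <- run_simulation(net, inlet, numerics = np)
  expect_false(identical(rs$P, rp$P))
})

test_that("negative geometry and missing probes are rejected before solving", {
  net <- single_vessel_net()
  net$probes <- net$probes[0, ]
  expect_error(run_simulation(net, constant_inflow(1e-5)), "probe")
})
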