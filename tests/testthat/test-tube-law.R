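test_that("tube law returns external pressure at zero distension and scales with sqrt area", {
  a0 <- pi * 0.003^2
  expect_equal(tube_law_pressure(a0, a0, 1000, 0), 0)
  expect_equal(tube_law_pressure(a0, a0, 1000, 250), 250)
  # sqrt(4) - 1 = 1: quadrupled area at beta = 1000 Pa gives 1000 Pa
  expect_equal(tube_law_pressure(4 * a0, a0, 1000, 0), 1000)
  # strictly increasing in area
  areas <- a0 * seq(0.5, 2, length.out = 20)
  p <- tube_law_pressure(areas, a0, 5e4)
  expect_true(all(diff(p) > 0))
  expect_error(tube_law_pressure(-1e-5, a0, 1000), "non-positive")
})

test_that("stiffness coefficient matches direct substitution for the renal artery", {
  # E = 400 kPa, h0 = 0.54 mm, nu = 0.5, r0 = 2.71 mm
  E <- 400e3; h0 <- 0.54e-3; r0 <- 2.71e-3; nu <- 0.5
  a0 <- pi * r0^2
  expected <- sqrt(pi / a0) * E * h0 / (1 - nu^2)   # direct substitution
  expect_equal(tube_beta(E, h0, r0, nu), expected)
  expect_equal(expected, E * h0 / ((1 - nu^2) * r0), tolerance = 1e-12)
})

test_that("wave speed scales as the square root of stiffness", {
  a0 <- pi * 0.005^2
  beta <- 1.2e5
  c1 <- wave_speed(a0, a0, beta)
  expect_equal(wave_speed(a0, a0, 4 * beta), 2 * c1)
  # c0^2 = beta / (2 rho) at the reference area
  expect_equal(c1^2, beta / (2 * 1060))
})

test_that("wave speed agrees with the numerical derivative of the tube law", {
  a0 <- pi * 0.004^2
  beta <- 2e5
  rho <- 1060
  for (a in a0 * c(0.8, 1, 1.3)) {
    dp_da <- (tube_law_pressure(a * (1 + 1e-7), a0, beta) -
              tube_law_pressure(a * (1 - 1e-7), a0, beta)) / (2e-7 * a)
    expect_equal(wave_speed(a, a0, beta, rho), sqrt(a / rho * dp_da),
                 tolerance = 1e-6)
  }
})

test_that("pressure unit conversion round-trips exactly", {
  x <- c(0.1, 93.3, 120, 250)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-12)
})
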