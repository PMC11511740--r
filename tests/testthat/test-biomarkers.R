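test_that("resistive index matches direct substitution", {
  # V_PSV = 100 cm/s, V_EDV = 30 cm/s -> RI = 0.70
  n <- 200
  t <- seq(0, 1, length.out = n)
  v <- 0.30 + 0.70 * pmax(0, sin(pi * t / 0.35))   # peak 1.0, floor 0.30
  expect_equal(resistive_index(v), 0.70, tolerance = 1e-4)
  # constant velocity -> 0; zero end-diastolic -> 1
  expect_equal(resistive_index(rep(0.5, 50)), 0)
  vz <- c(pmax(0, sin(pi * seq(0, 1, length.out = n) / 0.3)))
  expect_equal(resistive_index(vz), 1)
  expect_error(resistive_index(rep(-0.1, 10)), "non-positive")
})

test_that("RI is invariant under uniform velocity rescaling", {
  set.seed(3)
  v <- 0.2 + abs(stats::rnorm(120, 0.3, 0.2))
  for (k in c(0.1, 2, 35)) {
    expect_equal(resistive_index(k * v), resistive_index(v), tolerance = 1e-12)
  }
})

test_that("the late-third end-diastolic rule ignores the early-diastolic notch", {
  n <- 300
  t <- seq(0, 1, length.out = n)
  v <- 0.3 + pmax(0, sin(pi * t / 0.3))
  v[t > 0.32 & t < 0.38] <- 0.05   # reverse-flow notch after systole
  expect_equal(resistive_index(v, "late-third"), (1.3 - 0.3) / 1.3,
               tolerance = 1e-4)
  expect_equal(resistive_index(v, "cycle-min"), (1.3 - 0.05) / 1.3,
               tolerance = 1e-4)
})

test_that("mean flow converts cycle averages to ml/min", {
  # constant 5 ml/s -> 300 ml/min
  expect_equal(mean_flow(rep(5e-6, 100)), 300)
  # sinusoid about 6 ml/s -> 360 ml/min
  ph <- seq(0, 2 * pi, length.out = 201)[-201]
  expect_equal(mean_flow(6e-6 + 2e-6 * sin(ph)), 360, tolerance = 1e-9)
  expect_equal(mean_flow(rep(0, 10)), 0)
})

test_that("brachial pressures are the cycle extrema in mmHg", {
  ph <- seq(0, 2 * pi, length.out = 201)   # includes the exact extrema
  p <- mmhg_to_pa(93.3 + 20 * sin(ph))
  res <- structure(list(P = matrix(p, 1, dimnames = list("brachial", NULL))),
                   class = "simulation_result")
  bp <- brachial_pressures(res)
  expect_equal(unname(bp["SBP"]), 113.3, tolerance = 1e-6)
  expect_equal(unname(bp["DBP"]), 73.3, tolerance = 1e-6)
  # constant pressure gives SBP = DBP
  res2 <- structure(list(P = matrix(mmhg_to_pa(rep(100, 50)), 1,
                                    dimnames = list("brachial", NULL))),
                    class = "simulation_result")
  expect_equal(unname(brachial_pressures(res2)), c(100, 100))
  expect_error(brachial_pressures(res, probe = "missing"), "missing")
})

test_that("subject RI averages the segmental probes and totals add exactly", {
  n <- 100
  mkv <- function(ri) 1 - ri * (seq_len(n) > 2 * n / 3)  # PSV 1, EDV 1 - ri
  u <- rbind(mkv(0.6), mkv(0.7), mkv(0.8), mkv(0.7), mkv(0.7),
             mkv(0.6), mkv(0.7), mkv(0.8), mkv(0.7), mkv(0.7))
  rownames(u) <- sprintf("renal_seg_%s%d", rep(c("L", "R"), each = 5), rep(1:5, 2))
  res <- structure(list(u = u), class = "simulation_result")
  ri <- subject_RI(res)
  expect_equal(as.numeric(ri), 0.70, tolerance = 1e-9)
  expect_equal(attr(ri, "left"), 0.70, tolerance = 1e-9)
  # identical probes give the common value
  u2 <- u[rep(1, 10), ]
  rownames(u2) <- rownames(u)
  res2 <- structure(list(u = u2), class = "simulation_result")
  expect_equal(as.numeric(subject_RI(res2)), 0.60, tolerance = 1e-9)
})

test_that("biomarker records keep left+right = total exactly", {
  net <- build_baseline_network()
  res <- run_simulation(net, baseline_inlet())
  rec <- extract_biomarkers(res)
  expect_identical(rec$RBF_total, rec$RBF_left + rec$RBF_right)
  expect_identical(rec$RBF_single, (rec$RBF_left + rec$RBF_right) / 2)
  expect_gt(rec$SBP, rec$DBP)
  expect_true(rec$RI_mean >= 0 && rec$RI_mean <= 1)
})
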