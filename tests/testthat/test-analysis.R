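test_that("group summaries use type-7 quartiles and the 1.5 IQR outlier rule", {
  s <- summarize_groups(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  expect_equal(s$n_outliers, 0)
  # constant group: SD 0, no outliers
  s2 <- summarize_groups(rep(7, 12))
  expect_equal(s2$sd, 0)
  expect_equal(s2$n_outliers, 0)
  # one extreme point beyond Q3 + 1.5 IQR is flagged, and only that one
  x <- c(rnorm(50), 50)
  s3 <- summarize_groups(x)
  expect_true(50 %in% s3$outliers[[1]])
  expect_true(all(s3$outliers[[1]] < s3$q1[1] - 1.5 * s3$iqr[1] |
                  s3$outliers[[1]] > s3$q3[1] + 1.5 * s3$iqr[1]))
  # population SD, not sample SD
  expect_equal(summarize_groups(c(1, 3))$sd, 1)
})

test_that("ROC handles perfectly separated and exchangeable classes", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("HN", "DN"), each = 3), "DN")
  expect_equal(r$auc, 1.0)
  expect_equal(r$best$youden_j, 1.0)
  set.seed(42)
  x <- stats::rnorm(2000)
  r2 <- roc_analysis(x, rep(c("a", "b"), 1000), "a")
  expect_lt(abs(r2$auc - 0.5), 0.05)
  expect_error(roc_analysis(1:5, rep("DN", 5), "DN"), "classes")
})

test_that("trapezoidal AUC equals the pairwise concordance probability", {
  concordance_auc <- function(scores, labels, positive, dir) {
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    tot <- 0
    for (p in pos) for (q in neg) {
      cmp <- if (dir == ">") sign(p - q) else sign(q - p)
      tot <- tot + (cmp > 0) + 0.5 * (cmp == 0)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(8:25, 1)
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # ties likely
    labels <- sample(c("DN", "HN"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_analysis(scores, labels, "DN")
    expect_equal(r$auc, concordance_auc(scores, labels, "DN", r$direction),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(stats::rnorm(40, 1), stats::rnorm(40, 0))
  labels <- rep(c("DN", "HN"), each = 40)
  ours <- roc_analysis(scores, labels, "DN")
  ref <- pROC::roc(response = labels, predictor = scores, levels = c("HN", "DN"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("the reported cut-off attains the exhaustive-scan maximum of Youden's J", {
  set.seed(9)
  scores <- stats::rnorm(60)
  labels <- sample(c("DN", "HN"), 60, replace = TRUE)
  r <- roc_analysis(scores, labels, "DN")
  j <- r$sensitivity + r$specificity - 1
  expect_equal(r$best$youden_j, max(j))
  expect_true(r$best$cutoff %in% r$thresholds[j >= max(j) - 1e-12])
})

test_that("Sobol indices recover the analytic values of an additive model", {
  a <- c(x1 = 1, x2 = 2, x3 = 0.5)
  model <- function(m) m[, 1] * a[1] + m[, 2] * a[2] + m[, 3] * a[3]
  rng <- list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1))
  sr <- sobol_sensitivity(rng, model, base_n = 2048, seed = 2, n_boot = 100,
                          vectorized = TRUE)
  expect_s3_class(sr, "sobol_result")
  s1_true <- unname(a^2 / sum(a^2))
  expect_true(all(abs(sr$indices$S1 - s1_true) < 0.05))
  expect_true(all(abs(sr$indices$ST - s1_true) < 0.05))
  # additive: ST = S1 within CI slack
  expect_true(all(abs(sr$indices$ST - sr$indices$S1) < 0.05))
})

test_that("Sobol indices recover the Ishigami benchmark within CI", {
  a <- 7; b <- 0.1
  model <- function(m) sin(m[, 1]) + a * sin(m[, 2])^2 + b * m[, 3]^4 * sin(m[, 1])
  rng <- list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi))
  sr <- sobol_sensitivity(rng, model, base_n = 4096, seed = 3, n_boot = 100,
                          vectorized = TRUE)
  vx <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  s1_true <- c((b * pi^4 / 5 + b^2 * pi^8 / 50 + 0.5) / vx, (a^2 / 8) / vx, 0)
  st_true <- c(s1_true[1] + 8 * b^2 * pi^8 / 225 / vx, s1_true[2],
               8 * b^2 * pi^8 / 225 / vx)
  expect_true(all(abs(sr$indices$S1 - s1_true) < 0.07))
  expect_true(all(abs(sr$indices$ST - st_true) < 0.07))
  # total-order at least first-order (up to estimator noise)
  expect_true(all(sr$indices$ST >= sr$indices$S1 - 0.05))
})

test_that("calibration is a no-op when the target is already met", {
  sc <- disease_scalings("Early.D")
  ev <- function(s) 0.69
  out <- calibrate_stage(sc, target_RI = 0.69, evaluate = ev)
  expect_true(out$converged)
  expect_equal(out$n_eval, 1L)
  expect_equal(out$scaling$radius[["renal"]], sc$radius[["renal"]])
})

test_that("calibration moves only the renal tunables and reaches the target", {
  sc <- disease_scalings("Early.H")
  # synthetic monotone response: RI rises with renal PVR and falls with radius
  ev <- function(s) {
    0.55 + 0.25 * (s$PVR_renal %||% s$PVR) - 0.15 * s$radius[["renal"]]
  }
  `%||%` <- renopulse:::`%||%`
  out <- calibrate_stage(sc, target_RI = 0.75, evaluate = ev, max_eval = 50)
  expect_true(out$converged)
  expect_lt(abs(out$achieved_RI - 0.75) / 0.75, 0.05)
  # non-tunable multipliers untouched
  expect_identical(out$scaling$youngs_modulus, sc$youngs_modulus)
  expect_identical(out$scaling$cardiac_output, sc$cardiac_output)
  expect_identical(out$scaling$thickness, sc$thickness)
})
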