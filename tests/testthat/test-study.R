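# scaled-down structural runs of the study pipeline; quantitative checks
# live in the acceptance suite

fast_numerics <- numerics_config(convergence_tolerance = 0.02)

test_that("the ageing study produces per-group summaries and keep rates", {
  st <- run_ageing_study(n_per_group = 3, seed = 21,
                         groups = c("20-29", "70-79"),
                         numerics = fast_numerics)
  expect_true(all(c("biomarkers", "kept", "summary", "keep_report") %in%
                  names(st)))
  expect_setequal(unique(st$keep_report$age_group), c("20-29", "70-79"))
  expect_true(all(st$keep_report$keep_fraction >= 0 &
                  st$keep_report$keep_fraction <= 1))
  expect_setequal(unique(st$summary$variable),
                  c("SBP", "DBP", "RI_mean", "RBF_total"))
  expect_true(all(st$biomarkers$SBP > st$biomarkers$DBP))
  # rerun with the same seed is identical
  st2 <- run_ageing_study(n_per_group = 3, seed = 21,
                          groups = c("20-29", "70-79"),
                          numerics = fast_numerics)
  expect_identical(st$biomarkers, st2$biomarkers)
})

test_that("the disease study yields ROC results for both biomarkers and echoes its scalings", {
  st <- run_ageing_study(n_per_group = 4, seed = 33, groups = "50-59",
                         numerics = fast_numerics)
  subjects <- st$subjects
  skip_if(length(subjects) < 2, "too few filter-passing subjects at this n")
  ds <- run_disease_study(subjects, stages = c("Early.D", "Early.H"),
                          numerics = fast_numerics)
  expect_named(ds$roc, c("early_RBF", "early_RI"))
  expect_s3_class(ds$roc$early_RBF, "roc_result")
  expect_true(all(ds$biomarkers$stage %in% c("Early.D", "Early.H")))
  # the applied multipliers are the calibrated point values
  expect_equal(ds$scalings$Early.D$cardiac_output, 0.85)
  expect_equal(ds$scalings$Early.H$PVR, 1.15)
  expect_equal(nrow(ds$biomarkers), 2 * length(subjects) -
                 sum(unlist(ds$n_excluded)))
})

test_that("study configurations round-trip through their file format", {
  dir <- withr::local_tempdir()
  cfg <- study_config(n_per_group = c("20-29" = 10, "70-79" = 20), seed = 7,
                      groups = c("20-29", "70-79"), stages = "Early.D",
                      output_dir = "out")
  path <- file.path(dir, "cfg.json")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$n_per_group, cfg$n_per_group)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$groups, cfg$groups)
  expect_equal(unclass(back$numerics), unclass(cfg$numerics))
})

test_that("RI sensitivity screening separates influential from negligible factors", {
  model <- make_renal_ri_model()
  sr <- sobol_sensitivity(renal_ri_ranges(), model, base_n = 24, seed = 4,
                          n_boot = 50)
  st <- stats::setNames(sr$indices$ST, sr$indices$parameter)
  # the three renal calibration tunables all matter more than cardiac
  # output or viscosity, which barely move the resistive index
  for (p in c("renal_radius", "renal_PVR", "renal_PVC")) {
    expect_gt(st[[p]], st[["cardiac_output"]])
    expect_gt(st[[p]], st[["viscosity"]])
  }
  expect_true(all(sr$indices$ST > -0.05 & sr$indices$ST < 1.1))
})

test_that("raising renal-bed resistance raises the population mean RI", {
  st <- run_ageing_study(n_per_group = 3, seed = 55, groups = "50-59",
                         numerics = fast_numerics)
  subjects <- head(st$subjects, 3)
  skip_if(length(subjects) < 2, "too few filter-passing subjects at this n")
  ev <- make_mean_ri_evaluator(subjects, fast_numerics)
  lo <- identity_scaling(); lo$PVR_renal <- 1.0
  hi <- identity_scaling(); hi$PVR_renal <- 1.6
  expect_gt(ev(hi), ev(lo))
})
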