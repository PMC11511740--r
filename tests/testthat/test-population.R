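test_that("factor sampling is deterministic and truncated to (0, mean + 4 sd]", {
  s1 <- sample_ageing_subjects("50-59", 3, seed = 99)
  s2 <- sample_ageing_subjects("50-59", 3, seed = 99)
  expect_identical(s1[[1]]$factors, s2[[1]]$factors)
  expect_identical(s1[[3]]$network$vessels, s2[[3]]$network$vessels)
  tab <- ageing_table()
  for (s in s1) {
    f <- s$factors
    for (par in c("length", "radius", "youngs_modulus", "thickness")) {
      row <- tab[tab$age_group == "50-59" & tab$parameter == par, ]
      expect_true(all(f[[par]] > 0 & f[[par]] <= row$mean + 4 * row$sd))
    }
  }
  expect_error(sample_ageing_subjects("15-19", 3, seed = 1), "age group")
})

test_that("zero-SD distributions give every subject the baseline times the mean", {
  tab <- ageing_table()
  tab$sd <- 0
  subs <- sample_ageing_subjects("70-79", 2, seed = 5, table = tab)
  base <- build_baseline_network()
  m <- function(par) tab[tab$age_group == "70-79" & tab$parameter == par, "mean"]
  expect_equal(subs[[1]]$network$vessels$E, base$vessels$E * m("youngs_modulus"))
  expect_equal(subs[[1]]$network$vessels$length, base$vessels$length * m("length"))
  expect_equal(subs[[1]]$network$outlets$C, base$outlets$C * m("PVC"))
  expect_identical(subs[[1]]$network$vessels, subs[[2]]$network$vessels)
  expect_equal(subs[[1]]$inlet$cardiac_output,
               baseline_inlet()$cardiac_output * m("cardiac_output"))
})

test_that("disease scaling reproduces the published arithmetic", {
  subj <- local({
    tab <- ageing_table(); tab$sd <- 0
    sample_ageing_subjects("20-29", 1, seed = 1, table = tab)[[1]]
  })
  ed <- apply_disease_scaling(subj, disease_scalings("Early.D"))
  # renal artery radius 2.71 mm x 0.95 = 2.5745 mm
  expect_equal(ed$network$vessels$r_prox[ed$network$vessels$id == "renal_main_L"],
               2.5745e-3, tolerance = 1e-12)
  sd_ <- apply_disease_scaling(subj, disease_scalings("Severe.D"))
  # viscosity 4.00 mPa s x 1.20 = 4.80 mPa s
  expect_equal(sd_$blood$viscosity, 4.80e-3, tolerance = 1e-12)
  expect_equal(sd_$inlet$cardiac_output, subj$inlet$cardiac_output * 0.70)
  # identity scaling changes nothing
  id <- apply_disease_scaling(subj, identity_scaling())
  expect_equal(id$network$vessels, subj$network$vessels)
  expect_equal(id$network$outlets, subj$network$outlets)
  expect_equal(id$blood$viscosity, subj$blood$viscosity)
})

test_that("hypertension scales aortic segments together and others separately", {
  subj <- local({
    tab <- ageing_table(); tab$sd <- 0
    sample_ageing_subjects("20-29", 1, seed = 1, table = tab)[[1]]
  })
  eh <- apply_disease_scaling(subj, disease_scalings("Early.H"))
  v0 <- subj$network$vessels; v1 <- eh$network$vessels
  aorta <- grepl("aorta|aortic", v0$id)
  expect_equal(v1$r_prox[aorta] / v0$r_prox[aorta], rep(0.95, sum(aorta)))
  renal <- v0$role_tag != "systemic"
  expect_equal(unique(round(v1$r_prox[renal] / v0$r_prox[renal], 10)), 0.98)
  other <- !aorta & !renal
  expect_equal(unique(round(v1$r_prox[other] / v0$r_prox[other], 10)), 0.98)
})

test_that("disease scaling commutes with materialisation", {
  # scaling the factors then materialising equals materialising then scaling
  subj <- sample_ageing_subjects("40-49", 1, seed = 8)[[1]]
  ed1 <- apply_disease_scaling(subj, disease_scalings("Severe.H"))
  # route 2: scale the dimensional baseline first, then apply the factors
  base <- build_baseline_network()
  base_subj <- list(id = "b", age_group = "20-29", stage = "healthy",
                    factors = NULL, network = base,
                    inlet = baseline_inlet(1),
                    blood = blood_properties())
  class(base_subj) <- "virtual_subject"
  scaled_base <- apply_disease_scaling(base_subj, disease_scalings("Severe.H"))
  f <- subj$factors
  v2 <- scaled_base$network$vessels
  v2$r_prox <- v2$r_prox * f$radius[v2$id]
  expect_equal(v2$r_prox, ed1$network$vessels$r_prox, tolerance = 1e-12)
})

test_that("the physiology filter applies the 2.575-SD brachial window", {
  rec <- data.frame(age_group = "20-29",
                    SBP = c(120, 148.32, 148.33, 91.68, 150),
                    DBP = c(74, 74, 74, 74, 74))
  out <- physiology_filter(rec)
  # bounds: 120 +/- 2.575*11 = [91.675, 148.325]
  expect_identical(out$records$kept_flag, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # DBP violation alone removes a subject
  rec2 <- data.frame(age_group = "20-29", SBP = 120,
                     DBP = 74 + 2.575 * 8 + 0.01)
  expect_false(physiology_filter(rec2)$records$kept_flag)
  # degenerate SD keeps only exact means
  tab <- ageing_table()
  tab$sd[tab$parameter %in% c("SBP", "DBP")] <- 0
  rec3 <- data.frame(age_group = "20-29", SBP = c(120, 120.01), DBP = 74)
  expect_identical(physiology_filter(rec3, tab)$records$kept_flag, c(TRUE, FALSE))
})

test_that("the filter is idempotent and order-independent", {
  set.seed(10)
  rec <- data.frame(age_group = sample(age_groups(), 60, TRUE),
                    SBP = stats::rnorm(60, 122, 25),
                    DBP = stats::rnorm(60, 75, 15))
  once <- physiology_filter(rec)
  twice <- physiology_filter(once$kept[names(rec)])
  expect_equal(nrow(twice$kept), nrow(once$kept))
  perm <- sample(nrow(rec))
  shuffled <- physiology_filter(rec[perm, ])
  expect_setequal(rownames(shuffled$kept), rownames(once$kept))
})
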