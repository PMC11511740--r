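test_that("a two-vessel toy file parses into the expected network", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.csv")
  writeLines(c(
    "id,parent_ids,length_mm,r_prox_mm,r_dist_mm,h0_mm,E_kPa,nu,role_tag,outlet_R_total,outlet_C,outlet_r1_frac,outlet_p_out_Pa",
    "root,,100,10,9,1,400,0.5,systemic,,,,",
    "child,root,80,6,5,0.8,450,0.5,systemic,0.5,0.3,,0"), path)
  net <- read_network(path)
  expect_s3_class(net, "arterial_network")
  expect_equal(nrow(net$vessels), 2)
  expect_equal(length(network_junctions(net)), 1)
  expect_equal(nrow(net$outlets), 1)
  expect_equal(net$vessels$length, c(0.1, 0.08))
  expect_equal(net$outlets$R_total, 0.5e10)
  expect_equal(net$outlets$C, 0.3e-10)
  expect_equal(net$inlet_vessel_id, "root")
})

test_that("malformed vessels are rejected with the offending vessel named", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c(
    "id,parent_ids,length_mm,r_prox_mm,r_dist_mm,h0_mm,E_kPa,nu,role_tag,outlet_R_total,outlet_C",
    "root,,0,10,9,1,400,0.5,systemic,0.5,0.3"), path)
  expect_error(read_network(path), "root")
})

test_that("write/read round-trips random small trees field-for-field", {
  set.seed(42)
  dir <- withr::local_tempdir()
  for (i in 1:5) {
    net <- random_tree_net(n_extra = sample(3:8, 1))
    path <- file.path(dir, sprintf("net%d.csv", i))
    write_network(net, path)
    back <- read_network(path)
    expect_network_equal(net, back)
  }
})

test_that("round-trip preserves probe definitions", {
  dir <- withr::local_tempdir()
  net <- build_baseline_network()
  path <- file.path(dir, "baseline.csv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$probes, net$probes)
  expect_network_equal(net, back)
})

test_that("baseline fixture satisfies the published counts", {
  net <- build_baseline_network()
  expect_equal(nrow(net$vessels), 113)
  expect_equal(length(validate_network(net)), 0)
  for (side in c("L", "R")) {
    renal <- net$vessels$role_tag != "systemic" &
      grepl(paste0("_", side, "($|[0-9_])"), net$vessels$id)
    expect_equal(sum(renal), 38)
    expect_equal(sum(net$vessels$role_tag == "renal_segmental" & renal), 5)
  }
  expect_equal(sum(net$vessels$parent_ids == ""), 1)
  expect_equal(nrow(net$outlets), net$metadata$n_outlets)
})

test_that("baseline fixture carries the published model values", {
  net <- build_baseline_network()
  v <- function(id, col) net$vessels[net$vessels$id == id, col]
  expect_equal(v("renal_main_L", "r_prox"), 2.71e-3)
  expect_equal(v("ascending_aorta", "r_prox"), 15.95e-3)
  expect_equal(v("abdominal_aorta_b", "r_prox"), 7.49e-3)
  expect_equal(v("carotid_L", "r_prox"), 3.17e-3)
  expect_equal(v("radial_L", "r_prox"), 1.38e-3)
  expect_equal(v("renal_main_L", "h0"), 0.54e-3)
  expect_equal(v("carotid_L", "h0"), 0.70e-3)
  expect_equal(v("thoracic_aorta_a", "h0"), 2.12e-3)
  expect_true(all(net$vessels$E >= 400e3 & net$vessels$E <= 500e3))
  # outlet R-C-R parameters inside the published ranges
  expect_true(all(net$outlets$R_total >= 0.11e10 & net$outlets$R_total <= 17.20e10))
  expect_true(all(net$outlets$C >= 0.02e-10 & net$outlets$C <= 2.60e-10))
})

test_that("renal tree radii decrease monotonically with generation", {
  net <- build_baseline_network()
  ch <- network_children(net)
  renal <- net$vessels[net$vessels$role_tag != "systemic", ]
  for (i in seq_len(nrow(renal))) {
    for (kid in ch[[renal$id[i]]]) {
      expect_lt(net$vessels$r_prox[net$vessels$id == kid],
                renal$r_prox[i])
    }
  }
})

test_that("validation reports orphans, double inlets and bad geometry as findings", {
  net <- build_baseline_network()
  expect_identical(validate_network(net), character(0))
  bad <- net
  bad$vessels$parent_ids[bad$vessels$id == "celiac"] <- "no_such_vessel"
  f <- validate_network(bad)
  expect_true(any(grepl("celiac", f)))
  bad2 <- net
  bad2$vessels$parent_ids[bad2$vessels$id == "celiac"] <- ""
  f2 <- validate_network(bad2)
  expect_true(any(grepl("exactly one inlet", f2)))
  bad3 <- net
  bad3$vessels$length[5] <- 0
  expect_true(any(grepl("non-positive length", validate_network(bad3))))
  bad4 <- net
  bad4$vessels$r_dist[2] <- bad4$vessels$r_prox[2] * 1.1
  expect_true(any(grepl("distal radius", validate_network(bad4))))
})

test_that("the shipped baseline fixture file equals the programmatic builder", {
  path <- system.file("extdata", "baseline_network.csv", package = "renopulse")
  skip_if(path == "", "fixture file not installed")
  net <- read_network(path)
  expect_network_equal(net, build_baseline_network())
  expect_equal(net$metadata$n_vessels, 113)
})
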