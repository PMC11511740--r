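# small networks used across tests

# single uniform vessel with a lumped outlet
single_vessel_net <- function(length = 0.4, radius = 0.01, h0 = 0.0015,
                              E = 4e5, R = 1.2e8, C = 1e-8,
                              r1_frac = NA_real_, p_out = 0,
                              probe_fracs = c(inlet = 0.05, mid = 0.5)) {
  vessels <- data.frame(id = "v1", parent_ids = "", length = length,
                        r_prox = radius, r_dist = radius, h0 = h0, E = E,
                        nu = 0.5, role_tag = "systemic",
                        stringsAsFactors = FALSE)
  outlets <- data.frame(vessel_id = "v1", R_total = R, C = C,
                        r1_frac = r1_frac, p_out = p_out,
                        stringsAsFactors = FALSE)
  probes <- data.frame(name = names(probe_fracs), vessel_id = "v1",
                       frac = unname(probe_fracs), stringsAsFactors = FALSE)
  arterial_network(vessels, outlets, probes)
}

# parent bifurcating into two (by default identical) children
bifurcation_net <- function(r_parent = 0.008, r_child = 0.006,
                            r_child2 = r_child, E = 4e5) {
  mk <- function(id, parent, L, r, h) {
    data.frame(id = id, parent_ids = parent, length = L, r_prox = r,
               r_dist = r, h0 = h, E = E, nu = 0.5, role_tag = "systemic",
               stringsAsFactors = FALSE)
  }
  vessels <- rbind(mk("p", "", 0.2, r_parent, 0.0012),
                   mk("c1", "p", 0.15, r_child, 0.0009),
                   mk("c2", "p", 0.15, r_child2, 0.0009))
  outlets <- data.frame(vessel_id = c("c1", "c2"),
                        R_total = c(3e8, 3e8 * (r_child / r_child2)^3),
                        C = c(3e-9, 3e-9), r1_frac = NA_real_, p_out = 0,
                        stringsAsFactors = FALSE)
  probes <- data.frame(name = c("p_mid", "c1_mid", "c2_mid"),
                       vessel_id = c("p", "c1", "c2"), frac = 0.5,
                       stringsAsFactors = FALSE)
  arterial_network(vessels, outlets, probes)
}

# random small tree generator for round-trip property tests
random_tree_net <- function(n_extra = 5) {
  ids <- "root"
  rows <- list(data.frame(id = "root", parent_ids = "", length = 0.1,
                          r_prox = 0.01, r_dist = 0.009, h0 = 0.001,
                          E = 4e5, nu = 0.5, role_tag = "systemic",
                          stringsAsFactors = FALSE))
  for (i in seq_len(n_extra)) {
    parent <- sample(ids, 1)
    r <- stats::runif(1, 0.002, 0.008)
    rows[[length(rows) + 1]] <- data.frame(
      id = paste0("v", i), parent_ids = parent,
      length = stats::runif(1, 0.02, 0.3),
      r_prox = r, r_dist = r * stats::runif(1, 0.8, 1),
      h0 = stats::runif(1, 3e-4, 1.5e-3),
      E = stats::runif(1, 3e5, 8e5), nu = 0.5,
      role_tag = sample(c("systemic", "renal_interlobar"), 1),
      stringsAsFactors = FALSE)
    ids <- c(ids, paste0("v", i))
  }
  vessels <- do.call(rbind, rows)
  kids <- unlist(lapply(vessels$parent_ids, identity))
  terminals <- setdiff(vessels$id, kids)
  outlets <- data.frame(vessel_id = terminals,
                        R_total = stats::runif(length(terminals), 1e8, 1e10),
                        C = stats::runif(length(terminals), 1e-11, 1e-9),
                        r1_frac = ifelse(stats::runif(length(terminals)) < 0.5,
                                         NA_real_, 0.1),
                        p_out = 0, stringsAsFactors = FALSE)
  probes <- data.frame(name = "root_mid", vessel_id = "root", frac = 0.5,
                       stringsAsFactors = FALSE)
  arterial_network(vessels, outlets, probes)
}

expect_network_equal <- function(a, b) {
  expect_equal(a$vessels, b$vessels)
  oa <- a$outlets[order(a$outlets$vessel_id), ]
  ob <- b$outlets[order(b$outlets$vessel_id), ]
  rownames(oa) <- rownames(ob) <- NULL
  expect_equal(oa, ob)
  expect_equal(a$probes, b$probes)
  expect_equal(a$inlet_vessel_id, b$inlet_vessel_id)
}
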