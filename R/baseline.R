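# Baseline arterial-network fixture: a 37-vessel systemic tree plus, per
# side, a 38-vessel renal tree (1 main renal -> 5 segmental -> interlobar
# generations).  Named vessels carry the published model values (ascending
# aorta r = 15.95 mm, abdominal aorta r = 7.49 mm, carotid r = 3.17 mm,
# radial r = 1.38 mm, renal main r = 2.71 mm, descending-aorta h = 2.12 mm,
# carotid h = 0.70 mm, renal h = 0.54 mm, E = 400-500 kPa); the remaining
# geometry is documented fixture data in the anatomical ranges of the same
# tables (other radii 0.68-12.95 mm, other thickness 0.34-1.79 mm).

# Fixture haemodynamic targets used to allocate outlet R-C-R parameters.
# The distal pressure of every bed is 0; total resistances are set so the
# healthy young baseline carries the reference cardiac output at a mean
# arterial pressure of .BASE_MAP_PA, with a per-kidney flow of
# .RENAL_FLOW_MLMIN (half the reference total renal blood flow).  Bed
# compliances follow C = tau / R with bed-specific time constants, the
# single free dial that sets peripheral wave reflection and hence the
# diastolic decay of renal velocity (and so the resistive index).
.BASE_CO_M3S <- 5740 / .M3S_MLMIN      # 5.74 L/min reference cardiac output
.BASE_HR <- 70                          # beats/min, fixed for all subjects
.BASE_MAP_PA <- 12050                   # allocation MAP, ~90.4 mmHg
.RENAL_FLOW_MLMIN <- 517.5              # per-kidney allocation flow, ml/min
                                        # (delivers ~533 ml/min simulated once
                                        # the 1D tree impedance is in series)
.TAU_SYSTEMIC <- 0.60                   # systemic bed time constant, s
.TAU_RENAL <- 0.26                      # renal bed time constant, s
.PVC_CAP <- 2.6e-10                     # upper bound of bed compliance, m^3/Pa

# systemic tree: id, parent, length, r_prox, r_dist (mm), h0 (mm), E (kPa)
.systemic_table <- function() {
  r <- function(id, parent, L, rp, rd, h, E)
    data.frame(id = id, parent_ids = parent, L = L, rp = rp, rd = rd,
               h = h, E = E, stringsAsFactors = FALSE)
  do.call(rbind, list(
    r("ascending_aorta",   "",                  55, 15.95, 14.00, 0.85, 400),
    r("aortic_arch_a",     "ascending_aorta",   30, 12.95, 12.40, 0.85, 400),
    r("brachiocephalic",   "ascending_aorta",   34,  6.35,  6.00, 0.86, 400),
    r("carotid_L",         "aortic_arch_a",    177,  3.17,  3.17, 0.70, 400),
    r("aortic_arch_b",     "aortic_arch_a",     45, 12.40, 11.80, 0.85, 400),
    r("subclavian_R",      "brachiocephalic",   34,  4.25,  4.00, 0.67, 400),
    r("carotid_R",         "brachiocephalic",  177,  3.17,  3.17, 0.70, 400),
    r("subclavian_L",      "aortic_arch_b",     34,  4.25,  4.00, 0.67, 400),
    r("thoracic_aorta_a",  "aortic_arch_b",     52, 12.20, 11.40, 2.12, 400),
    r("vertebral_R",       "subclavian_R",     148,  1.36,  1.36, 0.45, 400),
    r("brachial_R",        "subclavian_R",     422,  3.24,  2.40, 0.67, 400),
    r("vertebral_L",       "subclavian_L",     148,  1.36,  1.36, 0.45, 400),
    r("brachial_L",        "subclavian_L",     422,  3.24,  2.40, 0.67, 400),
    r("radial_R",          "brachial_R",       235,  1.38,  1.38, 0.43, 400),
    r("ulnar_R",           "brachial_R",       229,  1.53,  1.45, 0.46, 400),
    r("radial_L",          "brachial_L",       235,  1.38,  1.38, 0.43, 400),
    r("ulnar_L",           "brachial_L",       229,  1.53,  1.45, 0.46, 400),
    r("thoracic_aorta_b",  "thoracic_aorta_a", 104, 11.40, 10.00, 2.12, 400),
    r("celiac",            "thoracic_aorta_b",  20,  3.90,  3.90, 0.64, 400),
    r("sup_mesenteric",    "thoracic_aorta_b",  59,  4.35,  4.35, 0.69, 400),
    r("abdominal_aorta_a", "thoracic_aorta_b",  53,  9.20,  8.50, 1.40, 400),
    r("abdominal_aorta_b", "abdominal_aorta_a",106,  7.49,  7.00, 1.25, 400),
    r("inf_mesenteric",    "abdominal_aorta_b", 50,  1.60,  1.60, 0.43, 400),
    r("common_iliac_R",    "abdominal_aorta_b", 58,  4.70,  4.50, 0.76, 400),
    r("common_iliac_L",    "abdominal_aorta_b", 58,  4.70,  4.50, 0.76, 400),
    r("external_iliac_R",  "common_iliac_R",   144,  3.20,  2.90, 0.60, 400),
    r("internal_iliac_R",  "common_iliac_R",    50,  2.00,  2.00, 0.54, 400),
    r("external_iliac_L",  "common_iliac_L",   144,  3.20,  2.90, 0.60, 400),
    r("internal_iliac_L",  "common_iliac_L",    50,  2.00,  2.00, 0.54, 400),
    r("femoral_R",         "external_iliac_R", 443,  2.60,  2.20, 0.55, 400),
    r("deep_femoral_R",    "external_iliac_R", 126,  2.00,  2.00, 0.52, 400),
    r("femoral_L",         "external_iliac_L", 443,  2.60,  2.20, 0.55, 400),
    r("deep_femoral_L",    "external_iliac_L", 126,  2.00,  2.00, 0.52, 400),
    r("anterior_tibial_R", "femoral_R",        343,  1.30,  1.10, 0.39, 400),
    r("posterior_tibial_R","femoral_R",        321,  1.55,  1.25, 0.42, 400),
    r("anterior_tibial_L", "femoral_L",        343,  1.30,  1.10, 0.39, 400),
    r("posterior_tibial_L","femoral_L",        321,  1.55,  1.25, 0.42, 400)))
}

# target mean flows of the systemic peripheral beds, ml/min, before
# normalisation to (CO - renal flow)
.SYSTEMIC_FLOWS <- c(
  carotid_L = 420, carotid_R = 420, vertebral_L = 120, vertebral_R = 120,
  radial_L = 110, radial_R = 110, ulnar_L = 130, ulnar_R = 130,
  celiac = 640, sup_mesenteric = 640, inf_mesenteric = 160,
  internal_iliac_L = 320, internal_iliac_R = 320,
  deep_femoral_L = 240, deep_femoral_R = 240,
  anterior_tibial_L = 130, anterior_tibial_R = 130,
  posterior_tibial_L = 147, posterior_tibial_R = 147)

# renal tree of one side: 1 main -> 5 segmental -> interlobar branches
# (breadth-first bifurcation until 38 vessels); interlobar radii follow
# Murray's law (r_parent^3 = sum r_child^3)
.renal_tree <- function(side, parent) {
  r <- function(id, parent, L, rp, rd, h, role)
    data.frame(id = id, parent_ids = parent, L = L, rp = rp, rd = rd,
               h = h, E = 400, role_tag = role, stringsAsFactors = FALSE)
  rows <- list(r(paste0("renal_main_", side), parent, 32, 2.71, 2.60,
                 0.54, "renal_main"))
  for (i in 1:5) {
    rows <- c(rows, list(r(sprintf("renal_seg_%s%d", side, i),
                           paste0("renal_main_", side),
                           18, 1.52, 1.40, 0.30, "renal_segmental")))
  }
  for (j in 1:10) {   # generation-1 interlobar, two per segmental
    rows <- c(rows, list(r(sprintf("renal_il1_%s%d", side, j),
                           sprintf("renal_seg_%s%d", side, (j + 1) %/% 2),
                           14, 1.11, 1.05, 0.22, "renal_interlobar")))
  }
  for (j in 1:20) {   # generation-2 interlobar, two per generation-1
    rows <- c(rows, list(r(sprintf("renal_il2_%s%d", side, j),
                           sprintf("renal_il1_%s%d", side, (j + 1) %/% 2),
                           10, 0.83, 0.79, 0.17, "renal_interlobar")))
  }
  for (j in 1:2) {    # generation-3 pair completing 38 vessels per side
    rows <- c(rows, list(r(sprintf("renal_il3_%s%d", side, j),
                           sprintf("renal_il2_%s1", side),
                           8, 0.63, 0.60, 0.13, "renal_interlobar")))
  }
  do.call(rbind, rows)
}

# mean-flow targets of the renal terminals of one subtree: descend from the
# per-kidney flow splitting at each junction in proportion to child r_prox^3
.renal_terminal_flows <- function(vessels, root_id, root_flow) {
  ch <- list()
  for (i in seq_len(nrow(vessels))) {
    p <- vessels$parent_ids[i]
    ch[[p]] <- c(ch[[p]], vessels$id[i])
  }
  flows <- c()
  recurse <- function(id, q) {
    kids <- ch[[id]]
    if (is.null(kids)) {
      flows[[id]] <<- q
      return(invisible())
    }
    w <- vessels$rp[match(kids, vessels$id)]^3
    for (k in seq_along(kids)) recurse(kids[k], q * w[k] / sum(w))
  }
  recurse(root_id, root_flow)
  unlist(flows)
}

#' Build the packaged baseline arterial network
#'
#' Constructs the 113-vessel reference network: a 37-vessel systemic tree
#' (aortic trunk, carotid, brachial/radial, visceral and iliac/femoral
#' branches) plus a 38-vessel renal tree per side (one main renal artery,
#' five segmental arteries, and bifurcating interlobar generations).
#' Outlet R-C-R parameters are allocated from target bed flows at the
#' reference cardiac output (5.74 L/min) and mean arterial pressure; the
#' proximal resistance of every outlet follows the characteristic-impedance
#' rule.  Probes are preconfigured at the two main renal artery midpoints,
#' the five segmental artery midpoints of each side, the left brachial
#' artery midpoint and the aortic root.
#'
#' @return a validated [arterial_network()] with fixture metadata
#'   (`n_vessels = 113`, `n_renal_per_side = 38`, and the actual outlet
#'   count of the reconstruction).
#' @export
build_baseline_network <- function() {
  sys <- .systemic_table()
  sys$role_tag <- "systemic"
  ren_l <- .renal_tree("L", "abdominal_aorta_a")
  ren_r <- .renal_tree("R", "abdominal_aorta_a")
  tab <- rbind(sys, ren_l, ren_r)
  vessels <- data.frame(id = tab$id, parent_ids = tab$parent_ids,
                        length = tab$L / 1000,
                        r_prox = tab$rp / 1000, r_dist = tab$rd / 1000,
                        h0 = tab$h / 1000, E = tab$E * 1000, nu = 0.5,
                        role_tag = tab$role_tag, stringsAsFactors = FALSE)

  renal_total <- 2 * .RENAL_FLOW_MLMIN
  sys_flows <- .SYSTEMIC_FLOWS *
    (.BASE_CO_M3S * .M3S_MLMIN - renal_total) / sum(.SYSTEMIC_FLOWS)
  ren_flows <- c(
    .renal_terminal_flows(ren_l, "renal_main_L", .RENAL_FLOW_MLMIN),
    .renal_terminal_flows(ren_r, "renal_main_R", .RENAL_FLOW_MLMIN))
  flows <- c(sys_flows, ren_flows)                  # ml/min
  q <- flows / .M3S_MLMIN                           # m^3/s
  r_tot <- .BASE_MAP_PA / q
  tau <- ifelse(names(flows) %in% names(sys_flows), .TAU_SYSTEMIC, .TAU_RENAL)
  outlets <- data.frame(vessel_id = names(flows), R_total = r_tot,
                        C = pmin(tau / r_tot, .PVC_CAP), r1_frac = NA_real_,
                        p_out = 0, stringsAsFactors = FALSE)

  probes <- rbind(
    data.frame(name = "aortic_root", vessel_id = "ascending_aorta", frac = 0.05),
    data.frame(name = "brachial", vessel_id = "brachial_L", frac = 0.5),
    data.frame(name = c("renal_main_L", "renal_main_R"),
               vessel_id = c("renal_main_L", "renal_main_R"), frac = 0.5),
    data.frame(name = sprintf("renal_seg_%s%d", rep(c("L", "R"), each = 5),
                              rep(1:5, 2)),
               vessel_id = sprintf("renal_seg_%s%d", rep(c("L", "R"), each = 5),
                                   rep(1:5, 2)),
               frac = 0.5))

  metadata <- list(
    n_vessels = nrow(vessels), n_outlets = nrow(outlets),
    n_renal_per_side = 38L, n_segmental_per_side = 5L,
    reference_cardiac_output_l_min = 5.74, heart_rate_bpm = .BASE_HR,
    note = paste("Reconstructed fixture: the anatomical source publishes 49",
                 "outlets; this reconstruction terminates every distal",
                 "interlobar branch in its own lumped R-C-R bed, giving the",
                 "outlet count recorded here."))
  arterial_network(vessels, outlets, probes, metadata)
}

#' Reference inlet waveform of the baseline network
#'
#' @param co_factor multiplicative cardiac-output scaling (1 = the 5.74
#'   L/min reference).
#' @return an `inlet_waveform` at the fixed 70 bpm reference heart rate.
#' @export
baseline_inlet <- function(co_factor = 1) {
  generate_inlet_waveform(.BASE_CO_M3S * co_factor, heart_rate = .BASE_HR)
}

#' Reduced aorto-renal network for sensitivity screening
#'
#' A compact network (aortic trunk, one renal main artery, five segmental
#' arteries) used where many model evaluations are required, e.g. Sobol
#' sensitivity screening of the renal resistive index.  Its outlets follow
#' the same allocation rules as the baseline fixture.
#'
#' @return an `arterial_network` with segmental probes.
#' @export
build_reduced_renal_network <- function() {
  r <- function(id, parent, L, rp, rd, h, E, role)
    data.frame(id = id, parent_ids = parent, L = L, rp = rp, rd = rd,
               h = h, E = E, role_tag = role, stringsAsFactors = FALSE)
  tab <- do.call(rbind, list(
    r("ascending_aorta", "", 60, 15.95, 12.40, 1.63, 400, "systemic"),
    r("thoracic_aorta", "ascending_aorta", 156, 11.60, 9.00, 2.12, 400, "systemic"),
    r("abdominal_aorta", "thoracic_aorta", 53, 8.60, 7.80, 1.40, 400, "systemic"),
    r("distal_aorta", "abdominal_aorta", 160, 7.49, 6.00, 1.25, 400, "systemic"),
    r("renal_main_L", "abdominal_aorta", 32, 2.71, 2.60, 0.54, 400, "renal_main")))
  for (i in 1:5) {
    tab <- rbind(tab, r(sprintf("renal_seg_L%d", i), "renal_main_L",
                        30, 1.52, 1.40, 0.30, 400, "renal_segmental"))
  }
  vessels <- data.frame(id = tab$id, parent_ids = tab$parent_ids,
                        length = tab$L / 1000,
                        r_prox = tab$rp / 1000, r_dist = tab$rd / 1000,
                        h0 = tab$h / 1000, E = tab$E * 1000, nu = 0.5,
                        role_tag = tab$role_tag, stringsAsFactors = FALSE)
  flows <- c(distal_aorta = 5740 - 2 * .RENAL_FLOW_MLMIN + .RENAL_FLOW_MLMIN,
             stats::setNames(rep(.RENAL_FLOW_MLMIN / 5, 5),
                             sprintf("renal_seg_L%d", 1:5)))
  q <- flows / .M3S_MLMIN
  r_tot <- .BASE_MAP_PA / q
  tau <- c(.TAU_SYSTEMIC, rep(.TAU_RENAL, 5))
  outlets <- data.frame(vessel_id = names(flows), R_total = r_tot,
                        C = pmin(tau / r_tot, .PVC_CAP), r1_frac = NA_real_,
                        p_out = 0, stringsAsFactors = FALSE)
  probes <- rbind(
    data.frame(name = "renal_main_L", vessel_id = "renal_main_L", frac = 0.5),
    data.frame(name = sprintf("renal_seg_L%d", 1:5),
               vessel_id = sprintf("renal_seg_L%d", 1:5), frac = 0.5))
  arterial_network(vessels, outlets, probes,
                   metadata = list(n_vessels = nrow(vessels),
                                   n_outlets = nrow(outlets)))
}
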