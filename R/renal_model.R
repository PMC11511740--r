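#' Grouped-parameter resistive-index model for sensitivity screening
#'
#' Builds an evaluator mapping nine grouped scaling factors — renal lumen
#' radius, renal-bed PVR, renal-bed PVC, systemic lumen radius, vessel
#' length, Young's modulus, wall thickness, cardiac output and blood
#' viscosity — to the mean segmental resistive index of a single simulated
#' subject.  Used for Sobol screening of which parameters drive RI and for
#' directional calibration probes; the compact aorto-renal network keeps
#' each evaluation cheap.
#'
#' @param baseline network to perturb (default the reduced aorto-renal
#'   network).
#' @param numerics a [numerics_config()]; a loose convergence tolerance is
#'   acceptable for screening.
#' @return function(named numeric vector of the nine factors) -> RI.
#' @export
make_renal_ri_model <- function(baseline = build_reduced_renal_network(),
                                numerics = numerics_config(
                                  convergence_tolerance = 0.02,
                                  max_cycles = 12)) {
  force(baseline); force(numerics)
  function(x) {
    v <- baseline$vessels
    renal <- v$role_tag != "systemic"
    rs <- ifelse(renal, x[["renal_radius"]], x[["radius"]])
    v$r_prox <- v$r_prox * rs
    v$r_dist <- v$r_dist * rs
    v$length <- v$length * x[["length"]]
    v$E <- v$E * x[["youngs_modulus"]]
    v$h0 <- v$h0 * x[["thickness"]]
    o <- baseline$outlets
    renal_o <- grepl("renal", o$vessel_id)
    o$R_total <- o$R_total * ifelse(renal_o, x[["renal_PVR"]], 1)
    o$C <- o$C * ifelse(renal_o, x[["renal_PVC"]], 1)
    net <- baseline
    net$vessels <- v
    net$outlets <- o
    inlet <- baseline_inlet(x[["cardiac_output"]])
    blood <- blood_properties(viscosity = 4.00e-3 * x[["viscosity"]])
    res <- run_simulation(net, inlet, blood, numerics)
    as.numeric(subject_RI(res))
  }
}

#' Default factor ranges for RI sensitivity screening
#'
#' Plus/minus 15% around unity for every grouped factor, the spread of the
#' ageing and disease scalings of the study.
#'
#' @param half_width half-width of each range.
#' @return named list of `c(min, max)` ranges for [sobol_sensitivity()].
#' @export
renal_ri_ranges <- function(half_width = 0.15) {
  nm <- c("renal_radius", "renal_PVR", "renal_PVC", "radius", "length",
          "youngs_modulus", "thickness", "cardiac_output", "viscosity")
  stats::setNames(rep(list(c(1 - half_width, 1 + half_width)), length(nm)), nm)
}
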