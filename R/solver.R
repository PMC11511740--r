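#' Run a pulse-wave simulation over an arterial network
#'
#' Advances the explicit MUSCL finite-volume scheme under a global CFL time
#' step, with the prescribed periodic inlet flow and R-C-R outlet coupling,
#' until the relative cycle-to-cycle max-norm change of the probe pressure
#' waveforms falls below the convergence tolerance (or `max_cycles` is
#' reached).  Returns the waveforms of the last simulated cycle at every
#' probe.
#'
#' @param net an [arterial_network()] with at least one probe.
#' @param inlet an `inlet_waveform` (see [generate_inlet_waveform()]).
#' @param blood a [blood_properties()] object.
#' @param numerics a [numerics_config()] object.
#' @return an object of class `simulation_result`: list with `t` (sample
#'   times within the cycle), matrices `P` (Pa), `Q` (m^3/s), `A` (m^2),
#'   `u` (m/s) of dimension probes x samples, plus `cycles_to_convergence`,
#'   `converged`, `convergence_error` and `mass_balance_error` (relative
#'   cycle volume imbalance).
#' @export
run_simulation <- function(net, inlet, blood = blood_properties(),
                           numerics = numerics_config()) {
  stopifnot(inherits(net, "arterial_network"),
            inherits(inlet, "inlet_waveform"))
  if (nrow(net$probes) == 0) {
    stop("network has no probes; add at least one measurement site")
  }
  if (is.na(numerics$init_pressure)) {
    # start somewhat below the subject's predicted mean arterial pressure
    # (charging the windkessels from below converges faster than
    # discharging them through the slow volume modes)
    r_par <- 1 / sum(1 / net$outlets$R_total)
    numerics$init_pressure <- max(0, 0.85 * inlet$cardiac_output * r_par)
  }
  res <- .cpp_run_simulation(net, inlet, blood, numerics, net$probes)
  res$period <- inlet$period
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d probes x %d samples, %d cycle(s), %s\n",
              nrow(x$P), ncol(x$P), x$cycles_to_convergence,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Solve the coupled interface states of a vessel junction
#'
#' Given the end states of one parent vessel (flow towards the junction)
#' and of its child vessels (flow away from it), computes interface states
#' satisfying (a) mass conservation, (b) continuity of total pressure
#' \eqn{P + \rho u^2/2}, and (c) invariance of the outgoing characteristic
#' of every vessel, by Newton iteration to a relative residual below
#' 1e-10.
#'
#' @param A_end lumen areas at the vessel ends, m^2; first element is the
#'   parent.
#' @param u_end velocities at the vessel ends, m/s (positive towards the
#'   periphery).
#' @param beta tube-law stiffness coefficients, Pa.
#' @param reference_area reference areas A0, m^2.
#' @param density blood density, kg/m^3.
#' @return list with interface `A`, `u`, `Q`, `total_pressure`, and the
#'   achieved `mass_residual_rel` and per-vessel `char_residual`.
#' @export
solve_junction <- function(A_end, u_end, beta, reference_area,
                           density = 1060) {
  stopifnot(length(A_end) >= 2, length(A_end) == length(u_end),
            length(A_end) == length(beta),
            length(A_end) == length(reference_area))
  .cpp_solve_junction(A_end, u_end, beta, reference_area, density)
}

#' Advance an R-C-R outlet model by one time step
#'
#' Reference (R-level) implementation of the lumped outlet update used at
#' every network outlet: the stored compartment pressure obeys
#' \deqn{C\, dP_c/dt = Q - (P_c - P_{out})/R_2}
#' and the interface pressure is \eqn{P = P_c + R_1 Q}.  The boundary flow
#' is taken from the vessel end state through the outgoing characteristic,
#' exactly as in the network solver.
#'
#' @param outlet list with `R1`, `R2`, `C`, `p_out` and stored pressure
#'   `Pc`.
#' @param end_state list with the vessel end state: `A` (m^2), `u` (m/s),
#'   `beta` (Pa), `A0` (m^2).
#' @param dt time step, s.
#' @param density blood density, kg/m^3.
#' @return list with interface `A`, `u`, `Q`, `P` (interface pressure) and
#'   the updated outlet (element `outlet`).
#' @export
windkessel_step <- function(outlet, end_state, dt, density = 1060) {
  stopifnot(dt > 0)
  b <- end_state$beta / sqrt(end_state$A0)
  k <- sqrt(b / (2 * density))
  cend <- k * end_state$A^0.25
  wp <- end_state$u + 4 * cend
  a <- end_state$A
  for (it in 1:100) {
    cc <- k * a^0.25
    u <- wp - 4 * cc
    p <- end_state$beta * (sqrt(a / end_state$A0) - 1)
    f <- p - outlet$Pc - outlet$R1 * a * u
    fp <- 0.5 * b / sqrt(a) - outlet$R1 * (u - cc)
    da <- f / fp
    a <- max(a - da, 0.1 * a)
    if (abs(da) < 1e-14 * a) break
  }
  u <- wp - 4 * k * a^0.25
  q <- a * u
  p_interface <- outlet$Pc + outlet$R1 * q
  outlet$Pc <- outlet$Pc + dt * (q - (outlet$Pc - outlet$p_out) / outlet$R2) / outlet$C
  list(A = a, u = u, Q = q, P = p_interface, outlet = outlet)
}
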