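#' Blood rheological properties
#'
#' @param density blood density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s (4.00 mPa s default).
#' @param profile_exponent velocity-profile shape parameter \eqn{\gamma_v};
#'   2 gives a parabolic (Poiseuille) profile for the viscous loss term.
#' @param coriolis_coefficient momentum-flux correction \eqn{\alpha};
#'   1 corresponds to a flat convective profile and makes the total-pressure
#'   junction coupling exact.
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1060, viscosity = 4.00e-3,
                             profile_exponent = 2, coriolis_coefficient = 1) {
  stopifnot(density > 0, viscosity > 0,
            profile_exponent >= 2, coriolis_coefficient >= 1)
  structure(list(density = density, viscosity = viscosity,
                 profile_exponent = profile_exponent,
                 coriolis_coefficient = coriolis_coefficient),
            class = "blood_properties")
}

#' Numerical settings for the finite-volume solver
#'
#' @param target_cell_size target axial cell size, m.
#' @param min_cells_per_vessel minimum number of cells in any vessel (>= 3).
#' @param cfl_number Courant number for the explicit time step, in (0, 1].
#' @param convergence_tolerance relative cycle-to-cycle max-norm change of
#'   probe pressure waveforms below which the solution is periodic.
#' @param max_cycles maximum number of cardiac cycles to advance.
#' @param samples_per_cycle number of output samples per cycle at each probe.
#' @param init_pressure initial uniform transmural pressure, Pa.  The
#'   converged periodic state does not depend on it; a physiological value
#'   shortens the transient.  `NA` (default) estimates the subject's mean
#'   arterial pressure as cardiac output times the parallel resistance of
#'   all outlet beds.  Set to 0 for a rest start.
#' @param friction_form `"standard"` uses the viscous source
#'   \eqn{-2(\gamma_v+2)\pi\mu Q/(\rho A)} in the momentum equation (Poiseuille
#'   limit for \eqn{\gamma_v = 2}); `"as-printed"` retains the literal
#'   \eqn{-2\mu(\gamma_v+2)Q/A} variant for comparison.
#' @return an object of class `numerics_config`.
#' @export
numerics_config <- function(target_cell_size = 1e-2, min_cells_per_vessel = 3,
                            cfl_number = 0.9, convergence_tolerance = 0.01,
                            max_cycles = 50, samples_per_cycle = 200,
                            init_pressure = NA_real_,
                            friction_form = c("standard", "as-printed")) {
  friction_form <- match.arg(friction_form)
  stopifnot(cfl_number > 0, cfl_number <= 1, min_cells_per_vessel >= 3,
            convergence_tolerance > 0, target_cell_size > 0,
            max_cycles >= 1, samples_per_cycle >= 16,
            is.na(init_pressure) || init_pressure >= 0)
  structure(list(target_cell_size = target_cell_size,
                 min_cells_per_vessel = as.integer(min_cells_per_vessel),
                 cfl_number = cfl_number,
                 convergence_tolerance = convergence_tolerance,
                 max_cycles = as.integer(max_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 init_pressure = init_pressure,
                 friction_form = friction_form),
            class = "numerics_config")
}
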