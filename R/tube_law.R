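#' Elastic tube law: transmural pressure at a given lumen area
#'
#' The vessel wall is modelled as a thin elastic membrane, giving the
#' algebraic pressure-area relation
#' \deqn{P(A) = P_{ext} + \beta\,(\sqrt{A/A_0} - 1)}
#' where \eqn{A_0} is the reference (zero-distension) lumen area and
#' \eqn{\beta} the wall stiffness coefficient (see [tube_beta()]).
#'
#' @param area lumen cross-sectional area, m^2 (vectorised).
#' @param reference_area reference area \eqn{A_0}, m^2.
#' @param beta wall stiffness coefficient, Pa.
#' @param external_pressure external (tissue) pressure, Pa.
#' @return pressure in Pa; strictly increasing in `area`.
#' @export
tube_law_pressure <- function(area, reference_area, beta, external_pressure = 0) {
  if (any(area <= 0)) stop("tube_law_pressure: non-positive area")
  if (any(reference_area <= 0)) stop("tube_law_pressure: non-positive reference area")
  external_pressure + beta * (sqrt(area / reference_area) - 1)
}

#' Wall stiffness coefficient of the elastic tube law
#'
#' \deqn{\beta = \sqrt{\pi/A_0}\; \frac{E h_0}{1 - \nu^2}}
#' with \eqn{A_0 = \pi r_0^2}, which reduces to
#' \eqn{\beta = E h_0 / ((1-\nu^2) r_0)}.
#'
#' @param youngs_modulus Young's modulus E, Pa.
#' @param wall_thickness reference wall thickness h0, m.
#' @param radius reference lumen radius r0, m.
#' @param poisson_ratio Poisson's ratio (0.5 for an incompressible wall).
#' @return stiffness coefficient in Pa.
#' @export
tube_beta <- function(youngs_modulus, wall_thickness, radius, poisson_ratio = 0.5) {
  a0 <- pi * radius^2
  sqrt(pi / a0) * youngs_modulus * wall_thickness / (1 - poisson_ratio^2)
}

#' Pulse wave speed of the elastic tube law
#'
#' From \eqn{c^2 = (A/\rho)\, dP/dA} applied to the tube law:
#' \deqn{c(A) = \sqrt{\beta / (2 \rho \sqrt{A_0})}\; A^{1/4}}
#' At \eqn{A = A_0} this reduces to \eqn{c_0 = \sqrt{\beta / (2\rho)}}.
#'
#' @param area lumen area, m^2 (vectorised).
#' @param reference_area reference area \eqn{A_0}, m^2.
#' @param beta wall stiffness coefficient, Pa.
#' @param density blood density, kg/m^3.
#' @return wave speed in m/s.
#' @export
wave_speed <- function(area, reference_area, beta, density = 1060) {
  stopifnot(all(area > 0), all(reference_area > 0), beta > 0, density > 0)
  sqrt(beta / (2 * density * sqrt(reference_area))) * area^0.25
}
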