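#' Parametric aortic inflow waveform
#'
#' Builds the periodic volumetric flow waveform imposed in the ascending
#' aorta: a systolic half-sine ejection lobe, a small early-diastolic
#' reverse lobe (valve closure), and zero flow in late diastole.  The
#' waveform is rescaled in amplitude so its cycle mean equals the cardiac
#' output and in period to `60/heart_rate`.
#'
#' @param cardiac_output cycle-mean flow, m^3/s.
#' @param heart_rate beats per minute.
#' @param shape template id; only `"aortic"` is provided.
#' @param n_samples number of samples describing one period.
#' @param systole_fraction fraction of the cycle occupied by the ejection
#'   lobe.
#' @param reverse_fraction fraction of forward lobe volume carried by the
#'   reverse lobe.
#' @return an object of class `inlet_waveform` with elements `period`,
#'   `time`, `flow_samples` and `cardiac_output`.
#' @export
generate_inlet_waveform <- function(cardiac_output, heart_rate = 70,
                                    shape = "aortic", n_samples = 512,
                                    systole_fraction = 0.31,
                                    reverse_fraction = 0.04) {
  stopifnot(cardiac_output > 0, heart_rate > 0, n_samples >= 64)
  if (!identical(shape, "aortic")) stop("unknown inlet waveform template: ", shape)
  period <- 60 / heart_rate
  ts <- systole_fraction          # ejection lobe, fraction of cycle
  tr <- 0.10                      # reverse lobe, fraction of cycle
  # forward amplitude such that the net cycle mean equals cardiac_output
  qf <- cardiac_output * pi / (2 * ts * (1 - reverse_fraction))
  qr <- reverse_fraction * qf * ts / tr
  s <- (seq_len(n_samples) - 1) / n_samples   # phase in [0, 1)
  q <- numeric(n_samples)
  sys <- s < ts
  q[sys] <- qf * sin(pi * s[sys] / ts)
  rev <- s >= ts & s < ts + tr
  q[rev] <- -qr * sin(pi * (s[rev] - ts) / tr)
  structure(list(period = period, time = s * period, flow_samples = q,
                 cardiac_output = cardiac_output),
            class = "inlet_waveform")
}

#' Steady (constant) inflow waveform, mainly for solver verification
#'
#' @param flow constant volumetric flow, m^3/s.
#' @param period nominal period, s (sets the cycle length for output and
#'   convergence bookkeeping).
#' @param n_samples samples per period.
#' @return an `inlet_waveform`.
#' @export
constant_inflow <- function(flow, period = 1, n_samples = 64) {
  s <- (seq_len(n_samples) - 1) / n_samples
  structure(list(period = period, time = s * period,
                 flow_samples = rep(flow, n_samples), cardiac_output = flow),
            class = "inlet_waveform")
}

#' Rescale an inlet waveform to a new cardiac output
#'
#' Amplitude scaling only: every sample is multiplied by the ratio of the
#' new to the old cycle mean.
#'
#' @param waveform an `inlet_waveform`.
#' @param cardiac_output new cycle-mean flow, m^3/s.
#' @return an `inlet_waveform`.
#' @export
scale_inlet_waveform <- function(waveform, cardiac_output) {
  k <- cardiac_output / waveform$cardiac_output
  waveform$flow_samples <- waveform$flow_samples * k
  waveform$cardiac_output <- cardiac_output
  waveform
}
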