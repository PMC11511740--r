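#' Renal resistive index of a velocity waveform
#'
#' \deqn{RI = (V_{PSV} - V_{EDV}) / V_{PSV}}
#' where \eqn{V_{PSV}} is the peak systolic velocity (cycle maximum) and
#' \eqn{V_{EDV}} the end-diastolic velocity.  By default the end-diastolic
#' velocity is the minimum over the final third of the cycle, which is
#' robust to the early-diastolic reverse-flow notch; `method = "cycle-min"`
#' uses the plain cycle minimum.
#'
#' @param velocity velocity samples over exactly one cycle, m/s (any
#'   uniform sampling).
#' @param method end-diastolic velocity definition.
#' @return dimensionless RI; equals 1 when `V_EDV` is 0, and lies in
#'   \[0, 1\] whenever `V_EDV >= 0`.
#' @export
resistive_index <- function(velocity, method = c("late-third", "cycle-min")) {
  method <- match.arg(method)
  if (!length(velocity)) stop("empty velocity series")
  vpsv <- max(velocity)
  if (vpsv <= 0) stop("non-positive peak systolic velocity")
  n <- length(velocity)
  vedv <- if (method == "late-third" && n >= 3) {
    min(velocity[(floor(2 * n / 3) + 1):n])
  } else {
    min(velocity)
  }
  (vpsv - vedv) / vpsv
}

#' Subject-level resistive index over the segmental probes
#'
#' Arithmetic mean of the per-probe RI over the ten segmental-artery
#' probes (five per kidney); per-side means are returned as attributes
#' `left` and `right`.
#'
#' @param result a `simulation_result`.
#' @param probe_pattern regular expression selecting the segmental probes.
#' @param method passed to [resistive_index()].
#' @return mean RI (with `left`/`right` attributes).
#' @export
subject_RI <- function(result, probe_pattern = "^renal_seg_",
                       method = "late-third") {
  probes <- grep(probe_pattern, rownames(result$u), value = TRUE)
  if (!length(probes)) stop("no segmental probes found in result")
  ri <- vapply(probes, function(p) resistive_index(result$u[p, ], method),
               numeric(1))
  out <- mean(ri)
  attr(out, "left") <- mean(ri[grepl("_L", probes)])
  attr(out, "right") <- mean(ri[grepl("_R", probes)])
  attr(out, "per_probe") <- ri
  out
}

#' Cycle-averaged volumetric flow in ml/min
#'
#' @param flow flow samples over exactly one cycle, m^3/s.
#' @return arithmetic time-average converted to ml/min.
#' @export
mean_flow <- function(flow) {
  mean(flow) * .M3S_MLMIN
}

#' Brachial systolic and diastolic pressure of a simulation
#'
#' @param result a `simulation_result` containing the brachial probe.
#' @param probe probe name.
#' @return named vector `c(SBP, DBP)` in mmHg (cycle maximum and minimum).
#' @export
brachial_pressures <- function(result, probe = "brachial") {
  if (!probe %in% rownames(result$P)) stop("missing probe: ", probe)
  p <- result$P[probe, ]
  c(SBP = pa_to_mmhg(max(p)), DBP = pa_to_mmhg(min(p)))
}

#' Extract the biomarker record of a simulated subject
#'
#' @param result a `simulation_result` from the subject's network (with
#'   brachial, main-renal and segmental probes).
#' @param subject the `virtual_subject` (for id/age group/stage metadata);
#'   optional.
#' @return one-row data.frame with columns `subject_id`, `age_group`,
#'   `stage`, `seed`, `SBP`, `DBP` (mmHg), `RI_mean`, `RI_left`,
#'   `RI_right`, `RBF_left`, `RBF_right`, `RBF_single`, `RBF_total`
#'   (ml/min) and `converged`.
#' @export
extract_biomarkers <- function(result, subject = NULL) {
  bp <- brachial_pressures(result)
  ri <- subject_RI(result)
  rbf_l <- mean_flow(result$Q["renal_main_L", ])
  rbf_r <- mean_flow(result$Q["renal_main_R", ])
  data.frame(
    subject_id = if (is.null(subject)) NA_character_ else subject$id,
    age_group = if (is.null(subject)) NA_character_ else subject$age_group,
    stage = if (is.null(subject)) NA_character_ else subject$stage,
    seed = if (is.null(subject$seed)) NA_integer_ else subject$seed,
    SBP = unname(bp["SBP"]), DBP = unname(bp["DBP"]),
    RI_mean = as.numeric(ri),
    RI_left = attr(ri, "left"), RI_right = attr(ri, "right"),
    RBF_left = rbf_l, RBF_right = rbf_r,
    RBF_single = (rbf_l + rbf_r) / 2,
    RBF_total = rbf_l + rbf_r,
    converged = isTRUE(result$converged),
    stringsAsFactors = FALSE)
}
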