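#' Calibrate renal multipliers of a disease stage to a target resistive
#' index
#'
#' Coordinate search (golden-section per coordinate, cycling) over the
#' three multipliers the resistive index is most sensitive to — renal
#' lumen radius, renal-bed PVR and renal-bed PVC — leaving every other
#' multiplier of the stage untouched, until the evaluated population mean
#' RI is within `tol` (relative) of the target or the evaluation budget is
#' exhausted.
#'
#' @param scaling the starting `disease_scaling`.
#' @param target_RI target population mean RI, in (0, 1).
#' @param evaluate function(`disease_scaling`) returning the achieved mean
#'   RI (e.g. built with [make_mean_ri_evaluator()]).
#' @param span half-width of the search interval around each starting
#'   multiplier, as a fraction (default 20%).
#' @param tol relative tolerance on |mean RI - target| / target.
#' @param max_eval maximum number of evaluator calls.
#' @return list with `scaling` (calibrated), `achieved_RI`, `converged`,
#'   `n_eval` and the search `trace`.
#' @export
calibrate_stage <- function(scaling, target_RI, evaluate, span = 0.2,
                            tol = 0.05, max_eval = 60) {
  stopifnot(target_RI > 0, target_RI < 1)
  get_tun <- function(s) c(
    renal_radius = unname(s$radius["renal"]),
    renal_PVR = s$PVR_renal %||% s$PVR,
    renal_PVC = s$PVC_renal %||% s$PVC)
  set_tun <- function(s, v) {
    s$radius["renal"] <- v[["renal_radius"]]
    s$PVR_renal <- v[["renal_PVR"]]
    s$PVC_renal <- v[["renal_PVC"]]
    s
  }
  n_eval <- 0L
  trace <- list()
  f <- function(v) {
    n_eval <<- n_eval + 1L
    ri <- evaluate(set_tun(scaling, v))
    trace[[length(trace) + 1L]] <<- c(v, RI = ri)
    ri
  }
  x <- get_tun(scaling)
  ri <- f(x)
  err <- function(r) abs(r - target_RI) / target_RI
  if (err(ri) < tol) {
    return(list(scaling = set_tun(scaling, x), achieved_RI = ri,
                converged = TRUE, n_eval = n_eval,
                trace = do.call(rbind, trace)))
  }
  gr <- (sqrt(5) - 1) / 2
  best <- list(x = x, ri = ri)
  repeat {
    improved <- FALSE
    for (coord in names(x)) {
      if (n_eval >= max_eval || err(best$ri) < tol) break
      a <- x[[coord]] * (1 - span)
      b <- x[[coord]] * (1 + span)
      # golden-section on |RI - target| along this coordinate
      c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
      xv <- x
      xv[[coord]] <- c1; f1 <- err(f(xv))
      xv[[coord]] <- c2; f2 <- err(f(xv))
      for (it in 1:8) {
        if (n_eval >= max_eval) break
        if (f1 < f2) {
          b <- c2; c2 <- c1; f2 <- f1
          c1 <- b - gr * (b - a)
          xv[[coord]] <- c1; f1 <- err(f(xv))
        } else {
          a <- c1; c1 <- c2; f1 <- f2
          c2 <- a + gr * (b - a)
          xv[[coord]] <- c2; f2 <- err(f(xv))
        }
        if (abs(b - a) < 1e-3 * x[[coord]]) break
      }
      xb <- if (f1 < f2) c1 else c2
      xv[[coord]] <- xb
      rib <- f(xv)
      if (err(rib) < err(best$ri)) {
        x <- xv
        best <- list(x = xv, ri = rib)
        improved <- TRUE
      }
    }
    if (err(best$ri) < tol || n_eval >= max_eval || !improved) break
  }
  list(scaling = set_tun(scaling, best$x), achieved_RI = best$ri,
       converged = err(best$ri) < tol, n_eval = n_eval,
       trace = do.call(rbind, trace))
}

#' Build a population-mean-RI evaluator for calibration
#'
#' Returns a function that applies a candidate `disease_scaling` to each
#' healthy subject of a (small) population, simulates, and returns the
#' population mean of the subject-level segmental RI.
#'
#' @param healthy_subjects list of healthy `virtual_subject`s.
#' @param numerics a [numerics_config()].
#' @return function(`disease_scaling`) -> mean RI.
#' @export
make_mean_ri_evaluator <- function(healthy_subjects,
                                   numerics = numerics_config()) {
  function(scaling) {
    ris <- vapply(healthy_subjects, function(s) {
      d <- apply_disease_scaling(s, scaling)
      res <- run_simulation(d$network, d$inlet, d$blood, numerics)
      as.numeric(subject_RI(res))
    }, numeric(1))
    mean(ris)
  }
}
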