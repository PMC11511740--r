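#' Normalised parameter distributions of the ageing model
#'
#' Per age group (20-29 to 70-79): mean and SD of the normalised scaling
#' factors for cardiac output, vessel length, lumen radius, Young's
#' modulus, wall thickness, peripheral resistance (PVR) and compliance
#' (PVC), plus the reference brachial SBP/DBP distributions (mmHg) used by
#' the physiology filter.
#'
#' @return data.frame with columns `age_group`, `parameter`, `mean`, `sd`.
#' @export
ageing_table <- function() {
  d <- utils::read.csv(system.file("extdata", "ageing_table.csv",
                                   package = "renopulse"),
                       stringsAsFactors = FALSE)
  stopifnot(length(unique(d$age_group)) == 6, all(d$sd >= 0), all(d$mean > 0))
  d
}

#' Age groups of the ageing model
#' @return character vector of the six age-group labels.
#' @export
age_groups <- function() {
  c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
}

#' Reference post-filter cohort sizes of the ageing populations
#'
#' Number of subjects (out of 2,000 sampled per group) retained by the
#' brachial-pressure physiology filter in the reference study; kept as
#' metadata for comparison with scaled-down runs.
#'
#' @return named integer vector by age group.
#' @export
ageing_group_counts <- function() {
  stats::setNames(c(759L, 822L, 701L, 711L, 655L, 605L), age_groups())
}

#' Calibrated disease-stage scalings
#'
#' Point multipliers of the four nephropathy stage models (Early.D,
#' Severe.D for diabetic; Early.H, Severe.H for hypertensive), as applied
#' deterministically to every healthy subject: global multipliers for
#' viscosity, cardiac output, PVR and PVC, and per-vessel-class multipliers
#' for lumen radius, Young's modulus and wall thickness (all aortic
#' segments share the aortic value).  Literature means/SDs are retained as
#' metadata in the `literature` element.
#'
#' @param stage optional stage id; if given, the single `disease_scaling`
#'   object is returned instead of the list of all four.
#' @return named list of `disease_scaling` objects (or one object).
#' @export
disease_scalings <- function(stage = NULL) {
  d <- utils::read.csv(system.file("extdata", "disease_scalings.csv",
                                   package = "renopulse"),
                       stringsAsFactors = FALSE)
  build <- function(s) {
    ds <- d[d$stage == s, ]
    pick <- function(par) {
      rows <- ds[ds$parameter == par, ]
      stats::setNames(rows$multiplier, rows$vessel_class)
    }
    scal <- list(stage = s,
                 viscosity = unname(pick("viscosity")["all"]),
                 cardiac_output = unname(pick("cardiac_output")["all"]),
                 radius = pick("radius"),
                 youngs_modulus = pick("youngs_modulus"),
                 thickness = pick("thickness"),
                 PVR = unname(pick("PVR")["all"]),
                 PVC = unname(pick("PVC")["all"]),
                 PVR_renal = NULL, PVC_renal = NULL,
                 literature = ds)
    stopifnot(all(unlist(scal[c("viscosity", "cardiac_output", "radius",
                                "youngs_modulus", "thickness", "PVR", "PVC")]) > 0))
    structure(scal, class = "disease_scaling")
  }
  stages <- unique(d$stage)
  if (!is.null(stage)) {
    if (!stage %in% stages) stop("unknown disease stage: ", stage)
    return(build(stage))
  }
  stats::setNames(lapply(stages, build), stages)
}

#' Identity scaling (no disease), useful for invariance checks
#' @return a `disease_scaling` with all multipliers equal to 1.
#' @export
identity_scaling <- function() {
  structure(list(stage = "healthy", viscosity = 1, cardiac_output = 1,
                 radius = c(other = 1), youngs_modulus = c(other = 1),
                 thickness = c(other = 1), PVR = 1, PVC = 1,
                 PVR_renal = NULL, PVC_renal = NULL,
                 literature = NULL),
            class = "disease_scaling")
}

# vessel class used to look up per-class disease multipliers
.vessel_class <- function(vessels) {
  ifelse(vessels$role_tag != "systemic", "renal",
  ifelse(grepl("aorta|aortic", vessels$id), "aorta",
  ifelse(grepl("carotid", vessels$id), "carotid",
  ifelse(grepl("radial", vessels$id), "radial",
  ifelse(grepl("brachial", vessels$id), "brachial", "other")))))
}

# look up per-vessel multipliers from a named class->multiplier vector;
# classes missing from the map fall back to "other" (or "all")
.class_multiplier <- function(classes, map) {
  fall <- if ("other" %in% names(map)) map[["other"]] else map[["all"]]
  out <- rep(fall, length(classes))
  hit <- classes %in% names(map)
  out[hit] <- map[classes[hit]]
  out
}

# truncated Gaussian on (0, mean + 4 sd], by rejection
.rtnorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  hi <- mean + 4 * sd
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0 | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0 | out[bad] > hi]
  }
  out
}

#' Sample per-vessel ageing scaling factors for one subject
#'
#' Each vessel receives independent Gaussian draws (truncated to
#' (0, mean+4sd]) for length, radius, Young's modulus and thickness; each
#' outlet for PVR and PVC; cardiac output is a single per-subject draw.
#'
#' @param table [ageing_table()].
#' @param age_group one of [age_groups()].
#' @param net the network the factors refer to (ids taken from it).
#' @return a `scaling_factor_set` (list of named factor vectors).
#' @keywords internal
.sample_factors <- function(table, age_group, net) {
  tt <- table[table$age_group == age_group, ]
  g <- function(par) tt[tt$parameter == par, c("mean", "sd")]
  ids <- net$vessels$id
  oid <- net$outlets$vessel_id
  draw <- function(par, k) {
    p <- g(par)
    .rtnorm(k, p$mean, p$sd)
  }
  structure(list(
    cardiac_output = draw("cardiac_output", 1),
    viscosity = 1,
    length = stats::setNames(draw("length", length(ids)), ids),
    radius = stats::setNames(draw("radius", length(ids)), ids),
    youngs_modulus = stats::setNames(draw("youngs_modulus", length(ids)), ids),
    thickness = stats::setNames(draw("thickness", length(ids)), ids),
    PVR = stats::setNames(draw("PVR", length(oid)), oid),
    PVC = stats::setNames(draw("PVC", length(oid)), oid),
    age_group = age_group, stage = "healthy"),
    class = "scaling_factor_set")
}

# materialize a subject network from baseline x factors
.materialize <- function(baseline, f) {
  v <- baseline$vessels
  v$length <- v$length * f$length[v$id]
  v$r_prox <- v$r_prox * f$radius[v$id]
  v$r_dist <- v$r_dist * f$radius[v$id]
  v$E <- v$E * f$youngs_modulus[v$id]
  v$h0 <- v$h0 * f$thickness[v$id]
  o <- baseline$outlets
  o$R_total <- o$R_total * f$PVR[o$vessel_id]
  o$C <- o$C * f$PVC[o$vessel_id]
  net <- baseline
  net$vessels <- v
  net$outlets <- o
  net
}

#' Sample healthy virtual subjects of one age group
#'
#' Draws `n` subjects whose per-vessel mechanical parameters are the
#' baseline values multiplied by independent Gaussian scaling factors from
#' the age-group rows of the ageing table; deterministic for a fixed seed.
#'
#' @param age_group one of [age_groups()].
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @param table [ageing_table()].
#' @param baseline baseline [arterial_network()].
#' @return list of `virtual_subject` objects: each has `id`, `age_group`,
#'   `stage`, `seed`, `factors`, a materialized `network`, an `inlet`
#'   waveform and `blood` properties.
#' @export
sample_ageing_subjects <- function(age_group, n, seed,
                                   table = ageing_table(),
                                   baseline = build_baseline_network()) {
  stopifnot(n > 0)
  if (!age_group %in% table$age_group) stop("unknown age group: ", age_group)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- .sample_factors(table, age_group, baseline)
    subj <- list(id = sprintf("%s_h_%04d", gsub("-", "", age_group), i),
                 age_group = age_group, stage = "healthy",
                 seed = seed, index = i, factors = f,
                 network = .materialize(baseline, f),
                 inlet = baseline_inlet(f$cardiac_output),
                 blood = blood_properties(viscosity = 4.00e-3 * f$viscosity))
    class(subj) <- "virtual_subject"
    subj
  })
}

#' Apply a calibrated disease-stage scaling to a healthy subject
#'
#' Multiplies every parameter of the materialized subject by the stage's
#' point multiplier: viscosity and cardiac output globally, radius /
#' Young's modulus / thickness by vessel class (all aortic segments share
#' the aortic trend), PVR and PVC at every outlet (renal-specific
#' overrides `PVR_renal` / `PVC_renal` are honoured when set, e.g. during
#' calibration).
#'
#' @param subject a healthy `virtual_subject`.
#' @param scaling a `disease_scaling` (see [disease_scalings()]).
#' @return a new `virtual_subject` carrying the stage id.
#' @export
apply_disease_scaling <- function(subject, scaling) {
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(scaling, "disease_scaling"))
  if (!identical(subject$stage, "healthy") &&
      !identical(scaling$stage, "healthy")) {
    stop("disease scalings apply to healthy subjects (got stage ",
         subject$stage, ")")
  }
  net <- subject$network
  cls <- .vessel_class(net$vessels)
  mr <- .class_multiplier(cls, scaling$radius)
  me <- .class_multiplier(cls, scaling$youngs_modulus)
  mh <- .class_multiplier(cls, scaling$thickness)
  net$vessels$r_prox <- net$vessels$r_prox * mr
  net$vessels$r_dist <- net$vessels$r_dist * mr
  net$vessels$E <- net$vessels$E * me
  net$vessels$h0 <- net$vessels$h0 * mh
  renal_out <- grepl("renal", net$outlets$vessel_id)
  pvr <- ifelse(renal_out & !is.null(scaling$PVR_renal),
                scaling$PVR_renal %||% scaling$PVR, scaling$PVR)
  pvc <- ifelse(renal_out & !is.null(scaling$PVC_renal),
                scaling$PVC_renal %||% scaling$PVC, scaling$PVC)
  net$outlets$R_total <- net$outlets$R_total * pvr
  net$outlets$C <- net$outlets$C * pvc
  out <- subject
  out$network <- net
  out$stage <- scaling$stage
  out$id <- sub("_h_", paste0("_", tolower(gsub("[^A-Za-z]", "", scaling$stage)), "_"),
                subject$id)
  out$blood <- blood_properties(
    density = subject$blood$density,
    viscosity = subject$blood$viscosity * scaling$viscosity,
    profile_exponent = subject$blood$profile_exponent,
    coriolis_coefficient = subject$blood$coriolis_coefficient)
  out$inlet <- scale_inlet_waveform(subject$inlet,
                                    subject$inlet$cardiac_output *
                                      scaling$cardiac_output)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brachial-pressure physiology filter
#'
#' A subject is kept iff its simulated brachial systolic and diastolic
#' pressures both lie within 2.575 standard deviations of the age-group
#' reference means of the ageing table.
#'
#' @param records data.frame with columns `age_group`, `SBP`, `DBP`
#'   (mmHg); typically a biomarker table.
#' @param table [ageing_table()].
#' @param n_sd width of the acceptance window in reference SDs.
#' @return list with `kept` (the subset of `records`, plus logical column
#'   `kept_flag` on the full table in `records`) and `report` (per-group
#'   sampled/kept counts and keep fraction).
#' @export
physiology_filter <- function(records, table = ageing_table(), n_sd = 2.575) {
  if (!all(c("age_group", "SBP", "DBP") %in% names(records))) {
    stop("records must carry age_group, SBP and DBP")
  }
  if (anyNA(records$SBP) || anyNA(records$DBP)) {
    stop("records contain missing brachial pressures")
  }
  ref <- function(group, par, what) {
    table[table$age_group == group & table$parameter == par, what]
  }
  ok <- vapply(seq_len(nrow(records)), function(i) {
    g <- records$age_group[i]
    abs(records$SBP[i] - ref(g, "SBP", "mean")) <= n_sd * ref(g, "SBP", "sd") &&
      abs(records$DBP[i] - ref(g, "DBP", "mean")) <= n_sd * ref(g, "DBP", "sd")
  }, logical(1))
  records$kept_flag <- ok
  rep <- do.call(rbind, lapply(unique(records$age_group), function(g) {
    sel <- records$age_group == g
    data.frame(age_group = g, n_sampled = sum(sel), n_kept = sum(ok[sel]),
               keep_fraction = mean(ok[sel]))
  }))
  list(kept = records[ok, , drop = FALSE], records = records, report = rep)
}
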