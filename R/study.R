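#' Simulate a list of virtual subjects and extract their biomarkers
#'
#' Runs the pulse-wave solver for every subject and collects the
#' biomarker records.  Subjects whose simulation fails or does not reach
#' periodic convergence are excluded from the biomarker table and counted
#' separately (they are reported, so they cannot be confused with the
#' physiology filter).
#'
#' @param subjects list of `virtual_subject`s.
#' @param numerics a [numerics_config()].
#' @param progress print a dot per subject.
#' @return list with `biomarkers` (data.frame), `n_excluded`,
#'   `excluded_ids` and `n_simulated`.
#' @export
simulate_population <- function(subjects, numerics = numerics_config(),
                                progress = FALSE) {
  rows <- vector("list", length(subjects))
  excluded <- character()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    rec <- tryCatch({
      res <- run_simulation(s$network, s$inlet, s$blood, numerics)
      if (!isTRUE(res$converged)) NULL else extract_biomarkers(res, s)
    }, error = function(e) NULL)
    if (is.null(rec)) excluded <- c(excluded, s$id) else rows[[i]] <- rec
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  list(biomarkers = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       n_excluded = length(excluded), excluded_ids = excluded,
       n_simulated = length(subjects))
}

#' Run the healthy-ageing study
#'
#' Samples virtual subjects per age group from the ageing distributions,
#' simulates them, applies the brachial-pressure physiology filter, and
#' summarises SBP, DBP, segmental RI and total renal blood flow per group.
#'
#' @param n_per_group subjects sampled per age group (scalar or named
#'   vector by group).
#' @param seed master seed; each group uses `seed + group index`.
#' @param groups age groups to include.
#' @param numerics a [numerics_config()].
#' @param table [ageing_table()].
#' @param baseline baseline network.
#' @param keep_subjects retain the healthy subject objects of the kept
#'   (filter-passing) records, for later disease scaling.
#' @return list with `biomarkers` (all simulated subjects, with
#'   `kept_flag`), `kept` (filter-passing records), `summary` (per-group
#'   stats for SBP/DBP/RI/RBF_total), `keep_report`, `n_excluded`, and
#'   (optionally) `subjects` (kept healthy subjects).
#' @export
run_ageing_study <- function(n_per_group = 50, seed = 1,
                             groups = age_groups(),
                             numerics = numerics_config(),
                             table = ageing_table(),
                             baseline = build_baseline_network(),
                             keep_subjects = TRUE) {
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  all_bio <- list()
  excluded <- 0L
  subj_store <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    subj <- sample_ageing_subjects(g, n_per_group[[g]],
                                   seed = seed + 1000L * gi,
                                   table = table, baseline = baseline)
    sim <- simulate_population(subj, numerics)
    all_bio[[g]] <- sim$biomarkers
    excluded <- excluded + sim$n_excluded
    if (keep_subjects) {
      keep <- vapply(subj, function(s)
        s$id %in% sim$biomarkers$subject_id, logical(1))
      subj_store <- c(subj_store, subj[keep])
    }
  }
  bio <- do.call(rbind, all_bio)
  rownames(bio) <- NULL
  flt <- physiology_filter(bio, table)
  kept <- flt$kept
  summ <- do.call(rbind, lapply(c("SBP", "DBP", "RI_mean", "RBF_total"),
    function(col) {
      s <- summarize_groups(kept[[col]], kept$age_group)
      s$variable <- col
      s
    }))
  if (keep_subjects) {
    keep_ids <- kept$subject_id
    subj_store <- Filter(function(s) s$id %in% keep_ids, subj_store)
  }
  list(biomarkers = flt$records, kept = kept, summary = summ,
       keep_report = flt$report, n_excluded = excluded,
       subjects = if (keep_subjects) subj_store else NULL,
       seed = seed)
}

#' Run the disease-population study
#'
#' Applies the calibrated stage scalings to each kept healthy subject,
#' simulates the diseased populations, and evaluates the ROC
#' discrimination between diabetic and hypertensive nephropathy (DN
#' positive) at the early and severe stages, with both the resistive
#' index and the single-kidney mean RBF as classifier scores.
#'
#' @param healthy_subjects list of kept healthy `virtual_subject`s (e.g.
#'   from [run_ageing_study()]).
#' @param stages stage ids to simulate.
#' @param numerics a [numerics_config()].
#' @param scalings list of `disease_scaling`s, by stage id.
#' @param roc_pairs named list of `c(positive, negative)` stage pairs to
#'   compare; DN is the positive class.
#' @return list with `biomarkers` (all stages), `n_excluded` per stage,
#'   `roc` (list of `roc_result` per pair x biomarker), and the applied
#'   `scalings`.
#' @export
run_disease_study <- function(healthy_subjects,
                              stages = c("Early.D", "Severe.D",
                                         "Early.H", "Severe.H"),
                              numerics = numerics_config(),
                              scalings = disease_scalings(),
                              roc_pairs = list(
                                early = c("Early.D", "Early.H"),
                                severe = c("Severe.D", "Severe.H"))) {
  bio <- list()
  excluded <- list()
  for (st in stages) {
    diseased <- lapply(healthy_subjects, apply_disease_scaling,
                       scaling = scalings[[st]])
    sim <- simulate_population(diseased, numerics)
    bio[[st]] <- sim$biomarkers
    excluded[[st]] <- sim$n_excluded
  }
  all_bio <- do.call(rbind, bio)
  rownames(all_bio) <- NULL
  roc <- list()
  for (pn in names(roc_pairs)) {
    pair <- roc_pairs[[pn]]
    if (!all(pair %in% stages)) next
    sel <- all_bio$stage %in% pair
    labs <- ifelse(all_bio$stage[sel] == pair[[1]], "DN", "HN")
    roc[[paste0(pn, "_RBF")]] <-
      roc_analysis(all_bio$RBF_single[sel], labs, "DN")
    roc[[paste0(pn, "_RI")]] <-
      roc_analysis(all_bio$RI_mean[sel], labs, "DN")
  }
  list(biomarkers = all_bio, n_excluded = excluded, roc = roc,
       scalings = scalings[stages])
}

#' Study configuration object
#'
#' Bundles the settings of an end-to-end run; round-trips through JSON via
#' [write_study_config()] / [read_study_config()].
#'
#' @param n_per_group subjects sampled per age group (scalar or named).
#' @param seed master seed.
#' @param groups age groups.
#' @param stages disease stages.
#' @param numerics a [numerics_config()].
#' @param output_dir where drivers write their tables.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_per_group = 50, seed = 1, groups = age_groups(),
                         stages = c("Early.D", "Severe.D", "Early.H",
                                    "Severe.H"),
                         numerics = numerics_config(),
                         output_dir = "results") {
  stopifnot(all(n_per_group > 0))
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 groups = groups, stages = stages, numerics = numerics,
                 output_dir = output_dir),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path JSON file path.
#' @export
write_study_config <- function(config, path) {
  x <- unclass(config)
  x$numerics <- unclass(x$numerics)
  if (!is.null(names(x$n_per_group))) {
    x$n_per_group <- as.list(x$n_per_group)   # keep group names in JSON
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- x$numerics
  cfg <- study_config(
    n_per_group = if (is.list(x$n_per_group) || length(x$n_per_group) > 1)
      unlist(x$n_per_group) else x$n_per_group,
    seed = x$seed, groups = x$groups, stages = x$stages,
    numerics = numerics_config(
      init_pressure = if (is.null(num$init_pressure)) NA_real_ else
        num$init_pressure,
      target_cell_size = num$target_cell_size,
      min_cells_per_vessel = num$min_cells_per_vessel,
      cfl_number = num$cfl_number,
      convergence_tolerance = num$convergence_tolerance,
      max_cycles = num$max_cycles,
      samples_per_cycle = num$samples_per_cycle,
      friction_form = num$friction_form),
    output_dir = x$output_dir)
  cfg
}
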