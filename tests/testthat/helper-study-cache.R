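# one shared scaled-down study run for the acceptance checks (computed on
# first use, then reused across test blocks)
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$run)) return(.study_cache$run)
  numerics <- numerics_config()
  n_per_group <- c("20-29" = 50, "30-39" = 50, "40-49" = 50,
                   "50-59" = 50, "60-69" = 50, "70-79" = 50)
  ageing <- run_ageing_study(n_per_group = n_per_group, seed = 20240901,
                             numerics = numerics)
  by_group <- split(ageing$subjects,
                    vapply(ageing$subjects, `[[`, "", "age_group"))
  cohort <- do.call(c, unname(lapply(by_group, utils::head, 10)))
  cohort_sd <- do.call(c, unname(lapply(by_group, utils::head, 8)))
  cohort_5059 <- utils::head(by_group[["50-59"]], 25)
  ids <- vapply(cohort, `[[`, "", "id")
  extra_5059 <- Filter(function(s) !s$id %in% ids, cohort_5059)
  scalings <- disease_scalings()
  stage_bio <- function(subjects, stage) {
    diseased <- lapply(subjects, apply_disease_scaling,
                       scaling = scalings[[stage]])
    simulate_population(diseased, numerics)$biomarkers
  }
  ed <- stage_bio(cohort, "Early.D")
  eh <- stage_bio(cohort, "Early.H")
  sdd <- stage_bio(cohort_sd, "Severe.D")
  ed_x <- stage_bio(extra_5059, "Early.D")
  eh_x <- stage_bio(extra_5059, "Early.H")
  grp <- function(b, g) b[b$age_group == g, , drop = FALSE]
  .study_cache$run <- list(
    ageing = ageing,
    ed = ed, eh = eh, sd = sdd,
    ed_5059 = rbind(grp(ed, "50-59"), ed_x),
    eh_5059 = rbind(grp(eh, "50-59"), eh_x))
  .study_cache$run
}
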