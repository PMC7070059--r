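#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume.
#
# Cohorts mirror the study designs: a serial-sampling oral PK cohort in
# colitic and naive mice (n = 10 per group, 2 mg/kg), a single-timepoint
# permeability plate (DSS n = 9, DSS+IL22Fc n = 10, naive n = 3), CLE
# severity cohorts (n = 10 per group), and ex vivo organ / IHC tables
# (n = 20 and n = 10 per group).

suppressPackageStartupMessages(library(nirperm))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 101
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

dose <- pk_dose(mg_per_kg = 2, route = "oral")

## --- serial-sampling PK cohorts -------------------------------------------
dss <- generate_pk_cohort(cohort_spec(
  "DSS", n = 10, params = default_pk_params("dss"), dose = dose,
  cv_ka = 0.3, cv_noise = 0.1, lod = 0.5, baseline_ng_ml = 0.5,
  seed = seed))
naive <- generate_pk_cohort(cohort_spec(
  "naive", n = 10, params = default_pk_params("naive"), dose = dose,
  cv_ka = 0.3, cv_noise = 0.1, lod = 0.5, baseline_ng_ml = 2,
  seed = seed + 1))

pk <- rbind(dss$data, naive$data)
class(pk) <- c("timecourse", "data.frame")
write_timecourse_csv(pk, file.path(out_dir, "pk_timecourses.csv"))
utils::write.csv(rbind(dss$truth, naive$truth),
                 file.path(out_dir, "pk_truth.csv"), row.names = FALSE)

## --- permeability plate (8 h single timepoint) ----------------------------
groups <- rep(c("DSS", "DSS+IL22Fc", "naive"), c(9, 10, 3))
means <- c(DSS = 6.7, `DSS+IL22Fc` = 1.3, naive = 0.5)[groups]
set.seed(seed + 2)
true_conc <- means * exp(stats::rnorm(length(means), 0, 0.35))
names(true_conc) <- sprintf("m%02d", seq_along(true_conc))
plate <- generate_plate(slope = 120, intercept = 60, blank_sd = 1.5,
                        sample_conc = true_conc, groups = groups,
                        dilution = 3, cv_noise = 0.05, seed = seed + 3)
utils::write.csv(plate$plate, file.path(out_dir, "plate.csv"),
                 row.names = FALSE)
utils::write.csv(data.frame(animal_id = names(true_conc), group = groups,
                            true_conc_ng_ml = true_conc),
                 file.path(out_dir, "plate_truth.csv"), row.names = FALSE)

## --- CLE severity cohorts -------------------------------------------------
cle_targets <- c(DSS = 4, `DSS+IL22Fc` = 1, naive = 0)
cle <- list()
for (g in names(cle_targets)) {
  cohort <- generate_cle_cohort(severity_cohort_spec(
    g, cle_targets[[g]], n = 10, frames_per_animal = 4,
    noise_rate = 0.15, seed = seed + 4 + match(g, names(cle_targets))))
  cle <- c(cle, cohort)
}
# one JSON line per frame, the rubric's exchange format
con <- file(file.path(out_dir, "cle_frames.jsonl"), "w")
for (animal in cle) {
  for (k in seq_along(animal$frames)) {
    rec <- c(list(animal_id = animal$animal_id, group = animal$group,
                  frame = k), unclass(animal$frames[[k]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
}
close(con)

## --- organ imaging and IHC tables -----------------------------------------
imaging <- generate_imaging_tables(
  group_mfi = c(DSS = 2400, `DSS+IL22Fc` = 950, naive = 900),
  group_pos_frac = c(DSS = 0.18, `DSS+IL22Fc` = 0.05, naive = 0.04),
  n = 20, marker = "NE", seed = seed + 8)
utils::write.csv(imaging$roi, file.path(out_dir, "roi_table.csv"),
                 row.names = FALSE)
utils::write.csv(imaging$ihc, file.path(out_dir, "ihc_areas.csv"),
                 row.names = FALSE)

write_provenance(file.path(out_dir, "provenance.json"), seed,
                 config = list(stage = "simulate_cohorts",
                               dose_mg_per_kg = 2,
                               cle_targets = as.list(cle_targets)))

cat("Synthetic inputs written to", out_dir, "\n")
cat(sprintf("  PK: %d animals x %d timepoints\n",
            length(unique(pk$animal_id)), length(unique(pk$time_h))))
cat(sprintf("  plate: %d wells; CLE: %d animals; imaging: %d ROIs\n",
            nrow(plate$plate), length(cle), nrow(imaging$roi)))
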