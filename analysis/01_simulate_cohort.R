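#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 230 training controls aged 20-84,
# 100 test controls, 194 patients with clinical covariates; write the subject
# table, one example subject volume + label atlas as NIfTI, and the
# ground-truth informative-voxel sets.

library(regionage)

out <- "results/01_cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 20260926L)
subjects <- generate_subjects(cfg)
write_subjects_tsv(subjects, file.path(out, "subjects.tsv"))

cat(sprintf("cohort: %d train HC, %d test HC, %d SCZ\n",
            sum(subjects$cohort == "train"),
            sum(subjects$group == "HC" & subjects$cohort == "test"),
            sum(subjects$group == "SCZ")))
cat(sprintf("ages: %.1f-%.1f (mean %.1f, sd %.1f)\n",
            min(subjects$chronological_age), max(subjects$chronological_age),
            mean(subjects$chronological_age), sd(subjects$chronological_age)))
scz <- subjects[subjects$group == "SCZ", ]
cat(sprintf("patients: duration %.1f +/- %.1f y, CPZ dose known for %d/%d\n",
            mean(scz$illness_duration), sd(scz$illness_duration),
            sum(!is.na(scz$cpz_dose)), nrow(scz)))

# one small GM atlas + the first subject's volume, as the on-disk interface
atlas <- make_grid_atlas("GM", n_regions = 6L, voxels_per_region = 50L)
maps <- generate_region_maps(subjects[1:10, ], atlas, cfg)
write_atlas_nifti(atlas, file.path(out, "atlas_gm_demo.nii.gz"))
write_subject_volume(maps, 1L, file.path(out, "subject1_gm_demo.nii.gz"))
jsonlite::write_json(maps$truth, file.path(out, "ground_truth_demo.json"))
cat("wrote", file.path(out, "subjects.tsv"),
    "and demo NIfTI volumes + ground truth\n")
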