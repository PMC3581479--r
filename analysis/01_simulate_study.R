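#!/usr/bin/env Rscript
# Generate and serialize a complete synthetic two-group multimodal study:
# a 23-pair bilateral gray-matter atlas with 4 white-matter ROIs, one
# resting-state BOLD session (1200 frames, TR 0.5 s), a cocaine-challenge
# phMRI study (12 wild-type vs 15 knockout subjects, 20 baseline + 80
# post-injection frames) and a diffusion phantom with a 50-direction
# b = 1250 s/mm^2 scheme. Everything lands under results/study/ with a JSON
# ground-truth sidecar, so downstream scripts can be run against files as
# well as in memory.

suppressPackageStartupMessages(library(ratconn))
seed <- 20240101L
out <- "results/study"

atlas <- make_atlas()
print(atlas)

fc_target <- example_fc_target(atlas)
rest <- sim_rest_bold(atlas, fc_target, n_frames = 1200, tr = 0.5,
                      voxel = FALSE, seed = seed)
cat("resting session:", nrow(rest$series$data), "ROI series x",
    ncol(rest$series$data), "frames\n")

phmri <- sim_phmri(n_subjects = c(12L, 15L), n_rois = 21L, seed = seed + 1L)
cat("phMRI study:", length(phmri$sessions), "subjects (",
    sum(phmri$ground_truth$group == "WT"), "WT /",
    sum(phmri$ground_truth$group == "KO"), "KO ),",
    nrow(phmri$sessions[[1]]$series), "ROIs each\n")

scheme <- make_scheme(n_directions = 50L, b = 1250, n_b0 = 2L, seed = seed)
cat("DWI scheme:", sum(scheme$b_values > 0), "weighted volumes, min angle",
    round(min_pairwise_angle(scheme$directions), 1), "deg\n")

write_study(out, atlas, rest = rest, phmri = phmri,
            ground_truth = list(
              fc_target = fc_target,
              phmri_group_means = phmri$ground_truth$group_means,
              phmri_ar1 = phmri$ground_truth$ar1_phi,
              seed = seed))
cat("study written to", out, "\n")
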