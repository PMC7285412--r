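#!/usr/bin/env Rscript
# Simulate one synthetic osteochondral disk at the full acquisition geometry
# (7 x 7 mm field, 15 x 15 x 32 um B-scan stack, 21 um isotropic micro-CT)
# and write the volumes plus ground truth for the downstream steps.
#
# Volumes are large and go to scratch/ (not tracked); summary tables and the
# true surface go to results/.

library(tidemark3d)

dir.create("scratch/disk01", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

params <- synth_params(seed = 20260921L)
gt <- generate_ground_truth(params)
cat(sprintf("true transform: %.2f deg rotation, (%.0f, %.0f, %.0f) um translation\n",
            rotation_angle_deg(gt$true_transform), gt$true_transform$t[1],
            gt$true_transform$t[2], gt$true_transform$t[3]))
cat(sprintf("CT tilt: %.1f deg; %.1f%% crack columns, %.1f%% hole columns\n",
            gt$tilt_deg, 100 * mean(gt$crack_mask), 100 * mean(gt$hole_mask)))

us <- simulate_us_volume(gt)
write_volume(us$volume, "scratch/disk01/us.json", format = "raw")
utils::write.table(us$approx, "scratch/disk01/approx_profile.csv",
                   sep = ",", row.names = FALSE, col.names = FALSE)
cat(sprintf("US stack: %d frames of %d x %d px\n", dim(us$volume)[1],
            dim(us$volume)[2], dim(us$volume)[3]))

ct <- simulate_ct_volume(gt)
write_volume(ct, "scratch/disk01/ct.json", format = "raw")
cat(sprintf("micro-CT: %d x %d x %d voxels\n", dim(ct)[1], dim(ct)[2], dim(ct)[3]))

truth <- true_surface_us_grid(gt)
write_surface(truth, "results/disk01_true_surface.csv", "csv")
write_surface(truth, "results/disk01_true_surface.stl", "stl")
saveRDS(gt, "scratch/disk01/ground_truth.rds")
cat(sprintf("true surface: %.0f-%.0f um depth over the field\n",
            min(truth$heights), max(truth$heights)))
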