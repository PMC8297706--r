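#!/usr/bin/env Rscript

# Phase diagram of landscape topology over regulation intensities.
#
# Sweeps a coarse (k1, k2) grid at fixed k3 (one slice per k3 value),
# recording joint peak counts and B/C marginal modalities per condition.
# The sweep is resumable: re-running the script skips conditions already
# present in the output CSV.
#
#   Rscript analysis/04_phase_diagram.R
#
# Runtime scales with the grid; the default 5 x 5 x 2 grid is roughly an
# hour of single-core time. Edit the axes below for denser maps.

suppressPackageStartupMessages(library(fflscape))

out_dir <- "results/phase_diagram"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

grid <- parameter_grid(
  k1 = c(0.2, 0.6, 1.2, 2.4, 4.8),
  k2 = c(0.2, 0.6, 1.2, 2.4, 4.8),
  k3 = c(0.5, 3.6)
)
write_grid_manifest(grid, file.path(out_dir, "manifest.csv"))

tab <- run_phase_diagram(grid, out_csv = file.path(out_dir, "topology.csv"))
print(table(tab$ffl_type, tab$joint_peaks))
message("wrote ", out_dir)
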