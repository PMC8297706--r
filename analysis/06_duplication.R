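#!/usr/bin/env Rscript

# Gene-duplication comparison, plus the input-intensity sweep.
#
# Part 1 re-solves a bimodal condition with genes b and c present in one or
# two copies; duplication adds promoter occupancy configurations and new
# synthesis levels, changing the number and position of probability peaks.
# Part 2 sweeps the input synthesis rate sA at fixed intensities and pairs
# each landscape with its mean-field C level.
#
#   Rscript analysis/06_duplication.R

suppressPackageStartupMessages(library(fflscape))

out_dir <- "results/duplication"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("== duplication ==")
# duplicating gene b at strong k1 doubles the accessible synthesis levels
# of B; duplicating both genes at the strongest intensities would exceed
# the 5e6-state guard, so the comparison is kept to the b axis
dup <- compare_duplication(ffl_params(3.0, 1, 1),
                           copies = data.frame(Nb = c(1, 2), Nc = c(1, 1)))
print(dup[, c("id", "n_states", "joint_peaks", "m_B", "m_C",
              "modes_B", "modes_C")])
write.csv(dup, file.path(out_dir, "duplication.csv"), row.names = FALSE)

message("== input intensity ==")
inp <- compare_input_intensity(ffl_params(3.0, 6.0, 3.6),
                               sA_values = c(2.5, 5, 10, 20))
print(inp[, c("id", "sA", "joint_peaks", "m_C", "modes_C", "ode_C")])
write.csv(inp, file.path(out_dir, "input_intensity.csv"), row.names = FALSE)
message("wrote ", out_dir)
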