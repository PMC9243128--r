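#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 219 controls vs 232 cases, 39
# compositional glycan peaks on 4 plates, group effects planted on the six
# component-1 peaks (GP34, GP32, GP26, GP31, GP36, GP30).
library(glycoblock)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = 1)
sim <- simulate_glycome(cfg)

write_peak_table(sim$peaks, "results/data/peaks.csv")
write_metadata(sim$meta, "results/data/metadata.csv")
writeLines(planted_truth(cfg), "results/data/planted_truth.txt")

message(sprintf("wrote %d samples x %d peaks (%d controls / %d cases, %d plates)",
                nrow(sim$peaks), ncol(sim$peaks),
                sum(sim$meta$group == "control"),
                sum(sim$meta$group == "case"),
                nlevels(sim$meta$batch)))
message("planted effect peaks: ", paste(planted_truth(cfg), collapse = ", "))
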