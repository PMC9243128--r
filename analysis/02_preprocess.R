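#!/usr/bin/env Rscript
# Preprocessing chain: ComBat batch correction -> median quotient
# normalisation -> rank transform, with a PCA plate-association check
# before and after.
library(glycoblock)

peaks <- read_peak_table("results/data/peaks.csv", tol = 1e-6)
meta <- read_metadata("results/data/metadata.csv")

before <- pca_batch_check(peaks, meta)
pre <- preprocess_glycome(peaks, meta)
after <- pca_batch_check(pre$processed, meta)

write_peak_table(pre$processed, "results/data/peaks_processed.csv")
write_peak_table(pre$normalized, "results/data/peaks_normalized.csv")
write.csv(rbind(cbind(stage = "raw", before),
                cbind(stage = "processed", after)),
          "results/pca_batch_check.csv", row.names = FALSE)
write.csv(data.frame(sample_id = names(pre$dilution_factors),
                     factor = pre$dilution_factors),
          "results/dilution_factors.csv", row.names = FALSE)

message(sprintf("PC1 plate association: p = %.2g before, p = %.2g after",
                before$p[1], after$p[1]))
message(sprintf("dilution factors span [%.3f, %.3f]",
                min(pre$dilution_factors), max(pre$dilution_factors)))
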