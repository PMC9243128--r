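#!/usr/bin/env Rscript
# Derived traits plus univariate screening: per-peak and per-trait
# Mann-Whitney tests with BH FDR control, and cluster-wise K/k counts.
library(glycoblock)

proc <- read_peak_table("results/data/peaks_processed.csv",
                        compositional = FALSE)
norm <- read_peak_table("results/data/peaks_normalized.csv",
                        compositional = FALSE)
meta <- read_metadata("results/data/metadata.csv")

traits <- suppressWarnings(compute_traits(norm))
write.csv(data.frame(sample_id = rownames(traits), traits),
          "results/derived_traits.csv", row.names = FALSE)

pk_cl <- ward_cluster(correlation_matrix(proc), k = 4, input = "correlation")
scr <- screen_features(proc, meta, clusters = pk_cl$labels)
write.csv(scr$results, "results/univariate_peaks.csv", row.names = FALSE)
write.csv(scr$clusters, "results/cluster_summary.csv", row.names = FALSE)

tr_scaled <- rank_transform(glycan_matrix(unclass(traits),
                                          compositional = FALSE),
                            standardize = TRUE)
scr_t <- screen_features(tr_scaled, meta)
write.csv(scr_t$results, "results/univariate_traits.csv", row.names = FALSE)

message(sprintf("%d / %d peaks and %d / %d traits at q < 0.05",
                sum(scr$results$q < 0.05), nrow(scr$results),
                sum(scr_t$results$q < 0.05), nrow(scr_t$results)))
for (i in seq_len(nrow(scr$clusters)))
  message(sprintf("cluster %s: K = %d, k = %d (p < 0.05)",
                  scr$clusters$cluster_id[i], scr$clusters$K[i],
                  scr$clusters$k[i]))
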