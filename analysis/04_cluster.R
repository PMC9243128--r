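#!/usr/bin/env Rscript
# Correlation signatures: Spearman peak-peak correlations, Ward (d = 1 - r)
# dendrogram cut at four clusters, and the clustered image map ordering.
library(glycoblock)

proc <- read_peak_table("results/data/peaks_processed.csv",
                        compositional = FALSE)
R <- correlation_matrix(proc)
wc <- ward_cluster(R, k = 4, input = "correlation")
cim <- clustered_image_map(R, row_input = "correlation",
                           col_input = "correlation", row_k = 4, col_k = 4)

write.csv(data.frame(peak = names(wc$labels), cluster = wc$labels),
          "results/peak_clusters.csv", row.names = FALSE)
writeLines(dendrogram_newick(wc$hclust), "results/peak_dendrogram.nwk")
write.csv(R[cim$row_hclust$order, cim$col_hclust$order],
          "results/correlation_cim.csv")

sizes <- table(wc$labels)
message("peak cluster sizes: ", paste(sizes, collapse = "/"))
truth <- planted_clusters(simulation_config())
message(sprintf("Rand index vs generator blocks: %.3f",
                rand_index(truth[names(wc$labels)], wc$labels)))
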