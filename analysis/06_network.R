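#!/usr/bin/env Rscript
# Relevance network between the peak and trait blocks at the |0.5| cut-off,
# plus circos-style Spearman edges among the selected variables.
library(glycoblock)

proc <- read_peak_table("results/data/peaks_processed.csv",
                        compositional = FALSE)
meta <- read_metadata("results/data/metadata.csv")
traits <- read.csv("results/derived_traits.csv", row.names = 1)
tr_scaled <- rank_transform(glycan_matrix(as.matrix(traits),
                                          compositional = FALSE),
                            standardize = TRUE)
g <- factor(meta$group[match(rownames(proc), meta$sample_id)],
            levels = c("control", "case"))
blocks <- list(peaks = unclass(proc), traits = unclass(tr_scaled))

fit <- fit_diablo(blocks, g, keepX = list(peaks = 10, traits = 10), D = 2)
S <- similarity_matrix(fit, "peaks", "traits", D_use = 1)
net <- build_network(S, threshold = 0.5, blocks = c("peaks", "traits"))
write_network(net, "results/network_edges.csv", format = "edge-list")
write_network(net, "results/network.graphml", format = "graphml")
write.csv(net$centrality, "results/network_centrality.csv",
          row.names = FALSE)

sel <- list(peaks = rank_loadings(fit, "peaks", d = 1, top = 10)$variable,
            traits = rank_loadings(fit, "traits", d = 1, top = 10)$variable)
ce <- circos_edges(blocks, sel, groups = g, threshold = 0.5)
write.csv(ce$edges, "results/circos_edges.csv", row.names = FALSE)
write.csv(ce$variables, "results/circos_variables.csv", row.names = FALSE)

deg <- net$degree[order(-net$degree$degree), ]
message(sprintf("network: %d edges at |0.5|; top hubs: %s",
                nrow(net$edges),
                paste(head(deg$name, 3), collapse = ", ")))
message(sprintf("circos: %d within-block + %d between-block edges",
                sum(ce$edges$type == "within"),
                sum(ce$edges$type == "between")))
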