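#!/usr/bin/env Rscript
# Multi-block discriminant analysis: peaks + derived traits + outcome,
# keepX = 10 per component, 80/20 stratified split, 5-fold CV, AUC.
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
sp <- split_train_test(g, fraction = 0.8, seed = 1)
tr <- lapply(blocks, function(b) b[sp$train, ]);
te <- lapply(blocks, function(b) b[sp$test, ])

fit <- fit_diablo(tr, g[sp$train],
                  keepX = list(peaks = 10, traits = 10), D = 2)
for (d in 1:2)
  write.csv(rank_loadings(fit, "peaks", d = d, top = 10),
            sprintf("results/top_loadings_comp%d.csv", d), row.names = FALSE)

auc_tr <- diablo_auc(fit, tr, g[sp$train])
auc_te <- diablo_auc(fit, te, g[sp$test])
cv <- cross_validate(blocks, g, folds = 5, repeats = 2, seed = 1,
                     keepX = list(peaks = 10, traits = 10), D = 2)
write.csv(data.frame(metric = c("auc_train", "auc_test",
                                "cv_balanced_error"),
                     value = c(auc_tr, auc_te, cv$balanced_error)),
          "results/discriminant_metrics.csv", row.names = FALSE)

message(sprintf("AUC: %.3f train, %.3f test; CV balanced error %.3f",
                auc_tr, auc_te, cv$balanced_error))
top1 <- rank_loadings(fit, "peaks", d = 1, top = 10)
message("component-1 peaks (most to least important): ",
        paste(top1$variable, collapse = ", "))
message("higher in: ", paste(top1$higher_in, collapse = ", "))
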