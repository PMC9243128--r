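#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end chain with defaults matching
#' the reference analysis settings: 80/20 stratified split, keepX = 10 on
#' the peak block per component, 2 components, 5-fold CV, relevance-network
#' cut-off |0.5|.
#'
#' @param ... overrides of the defaults listed below.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,             # generate synthetic data in-run
    sim = list(),                # overrides for simulation_config()
    peaks_file = NULL, meta_file = NULL,  # used when simulate = FALSE
    combat = TRUE, quotient = TRUE, ranks = TRUE,
    preserve_group = TRUE,
    rank_mode = "average-rank", rank_standardize = TRUE,
    traits_file = NULL,          # NULL -> shipped default table
    alpha = 0.05,
    peak_clusters = 4L, trait_clusters = 6L,
    keepX_peaks = 10L, keepX_traits = 10L,
    D = 2L,
    design_data = 1,
    split_fraction = 0.8,
    folds = 5L, cv_repeats = 2L,
    distance = "centroid-dist",
    network_threshold = 0.5, network_components = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis chain
#'
#' simulate/ingest -> preprocess -> derived traits -> univariate screening
#' -> cluster signatures -> multi-block discriminant (sGCCA/DIABLO with
#' train/test split, CV, AUC) -> relevance network. Artifacts are written
#' under `out_dir` as plain-text tables plus a machine-readable
#' `summary.json`; any stage failure aborts with the stage name, retaining
#' the artifacts written so far.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` for no files.
#' @param quiet suppress progress messages.
#' @return The summary list, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(name, obj) {
    if (!is.null(out_dir))
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage <- "ingest"
  summary <- list(seed = config$seed,
                  settings = list(keepX = config$keepX_peaks,
                                  threshold = config$network_threshold,
                                  split = config$split_fraction,
                                  D = config$D, folds = config$folds))
  res <- tryCatch({
    if (config$simulate) {
      stage <- "simulate"
      sim_cfg <- do.call(simulation_config,
                         c(config$sim, list(seed = config$seed)))
      sim <- simulate_glycome(sim_cfg)
      peaks <- sim$peaks; meta <- sim$meta
      summary$truth <- planted_truth(sim_cfg)
    } else {
      peaks <- read_peak_table(config$peaks_file)
      meta <- read_metadata(config$meta_file)
    }
    say("%s: %d samples x %d peaks", stage, nrow(peaks), ncol(peaks))
    summary$n_samples <- nrow(peaks); summary$n_peaks <- ncol(peaks)

    stage <- "preprocess"
    pre <- preprocess_glycome(peaks, meta, combat = config$combat,
                              quotient = config$quotient,
                              ranks = config$ranks,
                              preserve_group = config$preserve_group,
                              rank_mode = config$rank_mode,
                              rank_standardize = config$rank_standardize)
    pb <- pca_batch_check(pre$processed, meta)
    summary$pca_batch_p_comp1 <- pb$p[1]
    emit("pca_batch_check", pb)

    stage <- "traits"
    defs <- if (is.null(config$traits_file)) default_trait_definitions()
    else read_trait_definitions(config$traits_file)
    traits <- suppressWarnings(compute_traits(pre$normalized, defs))
    traits_proc <- rank_transform(
      glycan_matrix(unclass(traits), compositional = FALSE),
      mode = config$rank_mode, standardize = config$rank_standardize)
    summary$n_traits <- ncol(traits)

    stage <- "univariate"
    pk_cl <- ward_cluster(correlation_matrix(pre$processed),
                          k = config$peak_clusters, input = "correlation")
    scr <- screen_features(pre$processed, meta, alpha = config$alpha,
                           clusters = pk_cl$labels)
    emit("univariate_peaks", scr$results)
    emit("cluster_summary", scr$clusters)
    summary$n_significant_peaks <- sum(scr$results$q < config$alpha)
    summary$cluster_k <- scr$clusters$k
    summary$cluster_K <- scr$clusters$K

    stage <- "cluster"
    tr_cim <- clustered_image_map(unclass(traits_proc),
                                  col_input = "profiles",
                                  col_k = config$trait_clusters)
    summary$trait_cluster_sizes <-
      as.integer(table(tr_cim$col_labels))

    stage <- "integrate"
    g <- assert_two_groups(align_metadata(pre$processed, meta))
    blocks <- list(peaks = unclass(pre$processed),
                   traits = unclass(traits_proc))
    sp <- split_train_test(g, fraction = config$split_fraction,
                           seed = config$seed)
    tr_blocks <- lapply(blocks, function(b) b[sp$train, , drop = FALSE])
    te_blocks <- lapply(blocks, function(b) b[sp$test, , drop = FALSE])
    fit <- fit_diablo(tr_blocks, g[sp$train],
                      keepX = list(peaks = config$keepX_peaks,
                                   traits = config$keepX_traits),
                      D = config$D, design_data = config$design_data)
    summary$auc_train <- diablo_auc(fit, tr_blocks, g[sp$train])
    summary$auc_test <- diablo_auc(fit, te_blocks, g[sp$test])
    top <- rank_loadings(fit, "peaks", d = 1, top = config$keepX_peaks)
    emit("top_loadings_comp1", top)
    summary$top_peaks_comp1 <- top$variable
    cv <- cross_validate(blocks, g, folds = config$folds,
                         repeats = config$cv_repeats, seed = config$seed,
                         keepX = list(peaks = config$keepX_peaks,
                                      traits = config$keepX_traits),
                         D = config$D, distance = config$distance,
                         design_data = config$design_data)
    summary$cv_balanced_error <- cv$balanced_error

    stage <- "network"
    S <- similarity_matrix(fit, "peaks", "traits",
                           D_use = config$network_components)
    net <- build_network(S, threshold = config$network_threshold,
                         blocks = c("peaks", "traits"))
    summary$n_edges <- nrow(net$edges)
    summary$hub <- if (nrow(net$edges))
      net$degree$name[which.max(net$degree$degree)] else NA_character_
    if (!is.null(out_dir))
      write_network(net, file.path(out_dir, "network_edges.csv"),
                    format = "edge-list")
    summary
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(out_dir)) {
    jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
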