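#' Median quotient (probabilistic quotient) normalisation
#'
#' Per-sample dilution correction: each sample is divided by the median,
#' over features, of its ratio to a reference spectrum. The default
#' reference is the feature-wise median across samples.
#'
#' @param X a [glycan_matrix()]; all values must be strictly positive.
#' @param reference `"median-spectrum"` (default) or the id of an explicit
#'   reference sample.
#' @return List with `normalized` (non-compositional [glycan_matrix()]) and
#'   `factors` (named per-sample dilution factors).
#' @export
median_quotient_normalize <- function(X, reference = "median-spectrum") {
  M <- unclass(X)
  bad <- which(M <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("zero/negative entries not allowed for quotient normalisation: ",
         paste(sprintf("[%s,%s]", rownames(M)[bad[, 1]],
                       colnames(M)[bad[, 2]]),
               collapse = ", "))
  ref <- if (identical(reference, "median-spectrum")) {
    apply(M, 2, stats::median)
  } else {
    if (!reference %in% rownames(M))
      stop("reference sample not found: ", reference)
    M[reference, ]
  }
  factors <- apply(M, 1, function(r) stats::median(r / ref))
  out <- M / factors
  list(normalized = rewrap(out, X, compositional = FALSE), factors = factors)
}

#' Rank transformation
#'
#' Per-feature rank transform with average ranks for ties. The
#' inverse-normal mode maps ranks through the standard normal quantile with
#' the Blom offset, \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}. `standardize`
#' rescales average ranks to zero mean and unit variance (the form used by
#' the pipeline ahead of the multivariate stages).
#'
#' @param X a [glycan_matrix()] (no missing values).
#' @param mode `"average-rank"` (default) or `"inverse-normal"`.
#' @param standardize centre/scale average ranks (ignored for
#'   inverse-normal, which is already centred); default `FALSE`.
#' @return A non-compositional [glycan_matrix()] of transformed values.
#' @export
rank_transform <- function(X, mode = c("average-rank", "inverse-normal"),
                           standardize = FALSE) {
  mode <- match.arg(mode)
  M <- unclass(X)
  n <- nrow(M)
  out <- apply(M, 2, rank, ties.method = "average")
  if (mode == "inverse-normal") {
    const <- which(apply(M, 2, function(x) length(unique(x))) == 1L)
    if (length(const))
      stop("constant feature(s) cannot be inverse-normal transformed: ",
           paste(colnames(M)[const], collapse = ", "))
    out <- stats::qnorm((out - 3 / 8) / (n + 1 / 4))
  } else if (isTRUE(standardize)) {
    out <- scale(out)
    out[is.nan(out)] <- 0  # constant feature: all-tied ranks
  }
  rewrap(out, X, compositional = FALSE)
}

#' PCA batch-association check
#'
#' Centred SVD scores for the top components, each tested for association
#' with the plate factor by a rank-based one-way test (Kruskal-Wallis).
#' Used to confirm that plate clustering visible before batch correction is
#' gone afterwards.
#'
#' @param X a [glycan_matrix()] with at least 3 samples.
#' @param meta [sample_metadata()] carrying `batch`.
#' @param n_components number of leading components to test (default 5).
#' @return data.frame with `component`, `var_explained`, `statistic`, `df`,
#'   `p` per component.
#' @export
pca_batch_check <- function(X, meta, n_components = 5) {
  if (nrow(X) < 3) stop("need at least 3 samples for a PCA batch check")
  meta <- align_metadata(X, meta)
  batch <- droplevels(factor(meta$batch))
  pc <- stats::prcomp(unclass(X), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  res <- lapply(seq_len(k), function(j) {
    kt <- stats::kruskal.test(pc$x[, j], batch)
    data.frame(component = j, var_explained = ve[j],
               statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  })
  do.call(rbind, res)
}

#' Standard preprocessing chain
#'
#' Applies the stages in the fixed order batch correction, then median
#' quotient normalisation, then rank transform; each stage can be skipped.
#'
#' @param X a compositional [glycan_matrix()].
#' @param meta [sample_metadata()].
#' @param combat,quotient,ranks logical stage toggles.
#' @param preserve_group passed to [combat_correct()].
#' @param rank_mode,rank_standardize passed to [rank_transform()].
#' @return List with the final matrix (`processed`), the pre-rank matrix
#'   (`normalized`, the scale on which derived traits are computed), the
#'   batch model and the dilution factors (NULL for skipped stages).
#' @export
preprocess_glycome <- function(X, meta, combat = TRUE, quotient = TRUE,
                               ranks = TRUE, preserve_group = TRUE,
                               rank_mode = "average-rank",
                               rank_standardize = TRUE) {
  model <- NULL; factors <- NULL
  cur <- X
  if (combat) {
    cc <- combat_correct(cur, meta, preserve_group = preserve_group)
    cur <- cc$corrected; model <- cc$model
  }
  if (quotient) {
    if (any(unclass(cur) <= 0)) {
      # batch correction can push low-abundance cells to/below zero; shift
      # is not meaningful for quotients, so clip at a small positive floor
      eps <- 1e-8
      cur <- rewrap(pmax(unclass(cur), eps), cur, compositional = FALSE)
    }
    qn <- median_quotient_normalize(cur)
    cur <- qn$normalized; factors <- qn$factors
  }
  normalized <- cur
  if (ranks)
    cur <- rank_transform(cur, mode = rank_mode,
                          standardize = rank_standardize)
  list(processed = cur, normalized = normalized,
       batch_model = model, dilution_factors = factors)
}
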