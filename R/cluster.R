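#' Feature correlation matrix
#'
#' Spearman (default) or Pearson correlations between columns.
#'
#' @param X samples x features matrix, >= 3 rows.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  M <- unclass(X)
  if (nrow(M) < 3) stop("need at least 3 samples")
  const <- colnames(M)[apply(M, 2, stats::sd) == 0]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "))
  R <- stats::cor(M, method = method)
  (R + t(R)) / 2
}

#' Ward agglomerative clustering
#'
#' Ward's minimum-variance linkage via the Lance-Williams update on squared
#' Euclidean distances (heights on the distance scale, i.e. `ward.D2`).
#' Input is either a profile matrix (items in rows, Euclidean distances
#' computed), a `dist` object, or a correlation matrix converted to the
#' dissimilarity d = 1 - r with `input = "correlation"` — the default route
#' for clustering feature signatures.
#'
#' @param D profile matrix, `dist`, or square correlation matrix.
#' @param k number of clusters to cut (default 4).
#' @param input `"auto"`, `"profiles"`, `"distance"` or `"correlation"`.
#' @return List with `hclust` (the full stats::hclust tree: merges, heights,
#'   leaf order) and `labels` (cluster id per item from cutting at `k`).
#' @export
ward_cluster <- function(D, k = 4, input = c("auto", "profiles", "distance",
                                             "correlation")) {
  input <- match.arg(input)
  if (input == "auto") {
    input <- if (inherits(D, "dist")) "distance"
    else if (is.matrix(D) && nrow(D) == ncol(D) &&
             max(abs(D - t(D))) < 1e-12 && all(abs(D) <= 1 + 1e-12) &&
             all(abs(diag(D) - 1) < 1e-12)) "correlation"
    else "profiles"
  }
  d <- switch(input,
              distance = D,
              correlation = stats::as.dist(1 - D),
              profiles = stats::dist(unclass(D)))
  n <- attr(d, "Size")
  if (k > n) stop("k = ", k, " exceeds the number of items (", n, ")")
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels)
}

#' Clustered image map
#'
#' Independent Ward clusterings of the rows and columns of a matrix and the
#' matrix reordered by both leaf orders — the standard CIM used to display
#' pairwise association structure.
#'
#' @param M matrix, at least 2 x 2.
#' @param row_input,col_input passed to [ward_cluster()] as `input`
#'   (default `"profiles"`; for a square correlation matrix use
#'   `"correlation"`).
#' @param row_k,col_k cluster counts for the cut labels (defaults 2).
#' @return List with `row_hclust`, `col_hclust`, `row_labels`, `col_labels`,
#'   `matrix` (reordered).
#' @export
clustered_image_map <- function(M, row_input = "profiles",
                                col_input = "profiles",
                                row_k = 2, col_k = 2) {
  M <- unclass(M)
  if (nrow(M) < 2 || ncol(M) < 2) stop("matrix must be at least 2 x 2")
  rw <- ward_cluster(M, k = row_k, input = row_input)
  cw <- ward_cluster(t(M), k = col_k, input = col_input)
  list(row_hclust = rw$hclust, col_hclust = cw$hclust,
       row_labels = rw$labels, col_labels = cw$labels,
       matrix = M[rw$hclust$order, cw$hclust$order, drop = FALSE])
}

#' Serialize a dendrogram to Newick-like nested text
#'
#' @param hc an `hclust` object.
#' @param digits height precision.
#' @return A single character string, `(...)` nested with `:height` marks.
#' @export
dendrogram_newick <- function(hc, digits = 6) {
  lab <- if (is.null(hc$labels)) as.character(seq_len(nrow(hc$merge) + 1))
  else hc$labels
  node <- function(i, h_parent) {
    if (i < 0) return(sprintf("%s:%s", lab[-i], format(h_parent, digits = digits)))
    h <- hc$height[i]
    sprintf("(%s,%s):%s", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
            format(h_parent - h, digits = digits))
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  sprintf("(%s,%s);", node(hc$merge[top, 1], h), node(hc$merge[top, 2], h))
}

#' Adjusted-free Rand index between two partitions
#'
#' Proportion of item pairs on which two clusterings agree (same/different
#' cluster). Used to score recovery of planted block structure.
#'
#' @param a,b integer/factor labels of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
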