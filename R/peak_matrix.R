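#' Glycan peak matrix
#'
#' The central container of the package: a samples-by-peaks matrix of
#' relative abundances from a total plasma N-glycome chromatogram, where each
#' peak is quantified as a percentage of the total integrated area. Rows are
#' samples, columns are peaks (`GP1`..`GP39` by default). While the matrix is
#' *compositional* every row sums to 100; downstream transformations (batch
#' correction, rank transform) break closure and clear the flag.
#'
#' @param values numeric matrix, samples in rows, peaks in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `values`.
#' @param peak_ids character vector of unique peak names; defaults to the
#'   colnames of `values`.
#' @param compositional logical; assert row-closure to 100.
#' @param tol relative tolerance for the row-sum check (default `1e-6`).
#'
#' @return An object of class `glycan_matrix`: the numeric matrix with
#'   dimnames set and a `compositional` attribute.
#' @export
glycan_matrix <- function(values, sample_ids = rownames(values),
                          peak_ids = colnames(values),
                          compositional = TRUE, tol = 1e-6) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("peak values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(peak_ids)) stop("peak_ids are required")
  sample_ids <- as.character(sample_ids)
  peak_ids <- as.character(peak_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (length(peak_ids) != ncol(values))
    stop("peak_ids length does not match column count")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(peak_ids))
    stop("duplicate peak ids: ",
         paste(unique(peak_ids[duplicated(peak_ids)]), collapse = ", "))
  if (anyNA(values)) stop("missing values are not allowed in a glycan matrix")
  dimnames(values) <- list(sample_ids, peak_ids)
  if (isTRUE(compositional)) {
    if (any(values < 0))
      stop("negative abundances are not allowed in a compositional matrix")
    rs <- rowSums(values)
    bad <- which(abs(rs - 100) > tol * 100)
    if (length(bad))
      stop("rows do not sum to 100 (tolerance ", tol, "): sample(s) ",
           paste(sample_ids[bad], collapse = ", "),
           " with sums ", paste(signif(rs[bad], 8), collapse = ", "))
  }
  structure(values, class = c("glycan_matrix", "matrix", "array"),
            compositional = isTRUE(compositional))
}

#' @export
print.glycan_matrix <- function(x, ...) {
  cat(sprintf("glycan_matrix: %d samples x %d peaks (compositional=%s)\n",
              nrow(x), ncol(x), attr(x, "compositional")))
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))), seq_len(min(6L, ncol(x))),
                        drop = FALSE])
  invisible(x)
}

#' @rdname glycan_matrix
#' @param x object to test.
#' @export
is_glycan_matrix <- function(x) inherits(x, "glycan_matrix")

# Rebuild a glycan_matrix after a transformation, carrying names; the
# compositional flag must be stated explicitly by the caller.
rewrap <- function(values, template, compositional) {
  glycan_matrix(values, sample_ids = rownames(template),
                peak_ids = colnames(template),
                compositional = compositional)
}

#' Sample metadata
#'
#' Per-sample annotations joined to a [glycan_matrix()] by `sample_id`:
#' the two-level group factor (control/case), the plate (batch) identifier,
#' and any clinical covariates.
#'
#' @param df data.frame with at least columns `sample_id`, `group`, `batch`.
#' @return A validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "group", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  df$group <- factor(df$group)
  df$batch <- factor(df$batch)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

# Align metadata rows to the sample order of a glycan matrix; every sample
# must resolve to exactly one metadata row.
align_metadata <- function(X, meta) {
  idx <- match(rownames(X), meta$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(rownames(X)[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}

# Two-level group factor required by the discriminant stages.
assert_two_groups <- function(meta) {
  g <- droplevels(factor(meta$group))
  if (nlevels(g) != 2L)
    stop("group must have exactly two levels, got: ",
         paste(levels(g), collapse = ", "))
  g
}
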