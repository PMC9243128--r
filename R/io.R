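#' Read a glycan peak table from delimited text
#'
#' Expects a header row with a sample-id column (first column by default)
#' followed by one column per peak. Values are validated on read: non-numeric
#' cells, duplicate sample ids and broken row closure are all rejected before
#' any object is returned, so a failed read never yields a partially built
#' matrix.
#'
#' @param path file path.
#' @param delimiter field separator, `","` (default) or `"\t"`.
#' @param peaks expected peak panel; defaults to [default_peak_panel()].
#'   Pass `NULL` to accept whatever peak columns the file carries.
#' @param compositional validate row sums to 100 (default `TRUE`).
#' @param tol relative row-sum tolerance.
#' @param id_col name of the sample-id column; defaults to the first column.
#' @return A [glycan_matrix()].
#' @export
read_peak_table <- function(path, delimiter = ",", peaks = default_peak_panel(),
                            compositional = TRUE, tol = 1e-6, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (is.null(id_col)) id_col <- names(df)[1L]
  if (!id_col %in% names(df)) stop("sample-id column not found: ", id_col)
  ids <- as.character(df[[id_col]])
  df[[id_col]] <- NULL
  if (!is.null(peaks)) {
    absent <- setdiff(peaks, names(df))
    if (length(absent))
      stop("missing peak column(s): ", paste(absent, collapse = ", "))
    df <- df[peaks]
  }
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num))
    stop("non-numeric peak column(s): ", paste(not_num, collapse = ", "))
  glycan_matrix(as.matrix(df), sample_ids = ids, peak_ids = names(df),
                compositional = compositional, tol = tol)
}

#' Write a glycan peak table to delimited text
#'
#' @param X a [glycan_matrix()] (or plain numeric matrix with dimnames).
#' @param path output file path.
#' @param delimiter field separator.
#' @param digits significant digits to print (default 12, enough for an
#'   equal-at-12-decimals round trip of percent-scale data).
#' @export
write_peak_table <- function(X, path, delimiter = ",", digits = 12) {
  df <- data.frame(sample_id = rownames(X),
                   signif(unclass(X), digits + 3),
                   check.names = FALSE)
  # format with fixed decimals so read-back is bitwise-stable at `digits`
  for (j in seq(2L, ncol(df)))
    df[[j]] <- formatC(df[[j]], digits = digits, format = "f")
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from delimited text
#'
#' @inheritParams read_peak_table
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(utils::read.table(path, header = TRUE, sep = delimiter,
                                    stringsAsFactors = FALSE))
}

#' Write sample metadata
#' @param meta a [sample_metadata()] data.frame.
#' @inheritParams write_peak_table
#' @export
write_metadata <- function(meta, path, delimiter = ",") {
  utils::write.table(meta, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default peak panel
#'
#' The 39-peak panel of the total plasma N-glycome UPLC chromatogram.
#' @param n number of peaks (default 39).
#' @export
default_peak_panel <- function(n = 39) paste0("GP", seq_len(n))

#' Write a relevance network to disk
#'
#' Two formats: a flat edge list (`source, target, weight, source_block,
#' target_block`) and GraphML (via igraph, schema-valid XML).
#'
#' @param net a `relevance_network` (see [build_network()]).
#' @param path output file path.
#' @param format `"edge-list"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "relevance_network"))
  if (format == "edge-list") {
    ed <- net$edges
    ed$weight <- formatC(ed$weight, digits = 6, format = "f")
    utils::write.table(ed, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a relevance network edge list or GraphML file
#'
#' @param path file path.
#' @param format `"edge-list"` or `"graphml"`.
#' @return An igraph graph with `weight` edge attributes.
#' @export
read_network <- function(path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  ed <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed[c("source", "target")],
                                     directed = FALSE)
  if (nrow(ed)) igraph::E(g)$weight <- as.numeric(ed$weight)
  g
}

# igraph view of a relevance network (undirected, weighted, block attribute).
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("source", "target")], directed = FALSE,
    vertices = net$nodes)
  if (nrow(net$edges)) igraph::E(g)$weight <- net$edges$weight
  g
}
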