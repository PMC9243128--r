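#' Component-mediated similarity matrix between two blocks
#'
#' The standard relevance-network construction from a latent-component
#' model: for each dimension d, define \eqn{z_d} as the average of the two
#' blocks' component scores; the similarity of variable p (block i) and
#' variable q (block h) is \eqn{\sum_d cor(x_p, z_d)\,cor(x_q, z_d)},
#' clipped to \[-1, 1\]. Variable vectors are taken on the model's
#' centred/scaled training scale.
#'
#' @param model an `sgcca_model` or `diablo_model`.
#' @param block_i,block_h block names.
#' @param D_use number of leading dimensions to accumulate (default 1).
#' @return P_i x P_h similarity matrix.
#' @export
similarity_matrix <- function(model, block_i, block_h, D_use = 1) {
  core <- if (inherits(model, "diablo_model")) model$model else model
  for (b in c(block_i, block_h))
    if (!b %in% names(core$loadings)) stop("unknown block: ", b)
  if (D_use < 1 || D_use > core$D) stop("D_use out of range 1..", core$D)
  Xi <- core$blocks_scaled[[block_i]]
  Xh <- core$blocks_scaled[[block_h]]
  S <- matrix(0, ncol(Xi), ncol(Xh),
              dimnames = list(colnames(Xi), colnames(Xh)))
  for (d in seq_len(D_use)) {
    z <- (core$scores[[block_i]][, d] + core$scores[[block_h]][, d]) / 2
    ci <- drop(stats::cor(Xi, z))
    ch <- drop(stats::cor(Xh, z))
    S <- S + tcrossprod(ci, ch)
  }
  pmin(pmax(S, -1), 1)
}

#' Threshold a similarity matrix into a relevance network
#'
#' Keeps the (signed) edges whose absolute similarity reaches the cut-off,
#' producing a weighted bipartite graph across the two blocks plus a degree
#' table and eigenvector centralities for hub identification.
#'
#' @param S similarity matrix (rows = block-i variables, columns = block-h
#'   variables), e.g. from [similarity_matrix()].
#' @param threshold absolute-similarity cut-off in \[0, 1\] (default 0.5;
#'   values above 1 give an empty network).
#' @param blocks length-2 character: block names for rows and columns.
#' @return An object of class `relevance_network`: `nodes` (id, block),
#'   `edges` (source, target, weight, source_block, target_block),
#'   `threshold`, `degree` and `centrality` tables.
#' @export
build_network <- function(S, threshold = 0.5,
                          blocks = c("block1", "block2")) {
  keep <- which(abs(S) >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = rownames(S)[keep[, 1]],
                      target = colnames(S)[keep[, 2]],
                      weight = S[keep],
                      source_block = rep(blocks[1], nrow(keep)),
                      target_block = rep(blocks[2], nrow(keep)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(
    name = c(rownames(S), colnames(S)),
    block = rep(blocks, c(nrow(S), ncol(S))),
    stringsAsFactors = FALSE)
  # a variable present in both panels (same name) would collapse; keep ids
  # unique by block-qualifying duplicates
  dup <- duplicated(nodes$name)
  if (any(dup)) {
    qual <- paste(nodes$name, nodes$block, sep = ".")
    edges$source <- paste(edges$source, blocks[1], sep = ".")
    edges$target <- paste(edges$target, blocks[2], sep = ".")
    nodes$name <- qual
  }
  net <- structure(list(nodes = nodes, edges = edges, threshold = threshold),
                   class = "relevance_network")
  deg <- stats::setNames(rep(0, nrow(nodes)), nodes$name)
  if (nrow(edges)) {
    tab <- table(c(edges$source, edges$target))
    deg[names(tab)] <- as.numeric(tab)
  }
  net$degree <- data.frame(name = names(deg), block = nodes$block,
                           degree = as.numeric(deg),
                           stringsAsFactors = FALSE)
  net$centrality <- net$degree
  net$centrality$eigen <- if (nrow(edges)) {
    g <- as_igraph(net)
    ec <- igraph::eigen_centrality(g, weights = abs(igraph::E(g)$weight))$vector
    as.numeric(ec[net$degree$name])
  } else 0
  net
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("relevance_network: %d nodes, %d edges at |threshold| = %s\n",
              nrow(x$nodes), nrow(x$edges), format(x$threshold)))
  invisible(x)
}

#' Circos-style correlation edges among selected variables
#'
#' Pairwise Spearman (default) correlations among the variables selected
#' per block, computed on the supplied (preprocessed) data; edges with
#' \eqn{|r|} at or above the cut-off are returned with within/between-block
#' flags and a per-variable annotation of the class with the higher mean.
#'
#' @param data named list of samples x variables matrices (one per block,
#'   shared sample order).
#' @param selected named list of variable ids per block.
#' @param groups optional factor for the higher-mean annotation.
#' @param threshold absolute correlation cut-off (default 0.5).
#' @param method correlation method (default `"spearman"`).
#' @return List with `edges` (var1, var2, block1, block2, r, type) and
#'   `variables` (variable, block, higher_in).
#' @export
circos_edges <- function(data, selected, groups = NULL, threshold = 0.5,
                         method = "spearman") {
  blocks <- names(selected)
  cols <- list(); blk <- c()
  for (b in blocks) {
    absent <- setdiff(selected[[b]], colnames(data[[b]]))
    if (length(absent))
      stop("selected variable(s) absent from block '", b, "': ",
           paste(absent, collapse = ", "))
    cols[[b]] <- unclass(data[[b]])[, selected[[b]], drop = FALSE]
    blk <- c(blk, rep(b, length(selected[[b]])))
  }
  M <- do.call(cbind, cols)
  vn <- unlist(lapply(blocks, function(b) selected[[b]]), use.names = FALSE)
  colnames(M) <- vn
  R <- correlation_matrix(M, method = method)
  idx <- which(abs(R) >= threshold & upper.tri(R), arr.ind = TRUE)
  edges <- data.frame(var1 = vn[idx[, 1]], var2 = vn[idx[, 2]],
                      block1 = blk[idx[, 1]], block2 = blk[idx[, 2]],
                      r = R[idx], stringsAsFactors = FALSE)
  edges$type <- ifelse(edges$block1 == edges$block2, "within", "between")
  vars <- data.frame(variable = vn, block = blk, stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    g <- droplevels(factor(groups))
    vars$higher_in <- vapply(seq_along(vn), function(i) {
      m <- tapply(M[, i], g, mean)
      names(m)[which.max(m)]
    }, character(1))
  }
  list(edges = edges, variables = vars)
}
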