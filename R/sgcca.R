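#' Prepare a block set for multi-block analysis
#'
#' The integrative stages operate on J blocks \eqn{X^{(1)},...,X^{(J)}}
#' sharing the same N samples, each column centred to mean 0 and scaled to
#' unit variance. Centring/scaling parameters are stored so held-out data
#' can be mapped onto the training scale.
#'
#' @param blocks named list of samples x variables matrices with identical
#'   rownames in identical order.
#' @param scale scale columns to unit variance (default `TRUE`).
#' @return An object of class `block_set`: list with `blocks` (scaled),
#'   `centers`, `scales`, `sample_ids`.
#' @export
block_set <- function(blocks, scale = TRUE) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list")
  ids <- rownames(blocks[[1]])
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(rownames(b)) || !identical(rownames(b), ids))
      stop("block '", nm, "' does not share the sample order of block '",
           names(blocks)[1], "'")
  }
  centers <- scales <- vector("list", length(blocks))
  names(centers) <- names(scales) <- names(blocks)
  out <- blocks
  for (nm in names(blocks)) {
    M <- unclass(blocks[[nm]])
    ctr <- colMeans(M)
    scl <- if (scale) apply(M, 2, stats::sd) else rep(1, ncol(M))
    if (any(scl == 0))
      stop("constant column(s) in block '", nm, "': ",
           paste(colnames(M)[scl == 0], collapse = ", "))
    out[[nm]] <- sweep(sweep(M, 2, ctr), 2, scl, "/")
    centers[[nm]] <- ctr; scales[[nm]] <- scl
  }
  structure(list(blocks = out, centers = centers, scales = scales,
                 sample_ids = ids), class = "block_set")
}

# Apply stored centring/scaling to new data with the same variable panels.
# Any subset of the training blocks may be supplied (deflation and scoring
# are per-block operations); unknown block names are an error.
scale_like <- function(bs, new_blocks) {
  unknown <- setdiff(names(new_blocks), names(bs$blocks))
  if (length(unknown))
    stop("unknown block(s): ", paste(unknown, collapse = ", "))
  use <- intersect(names(bs$blocks), names(new_blocks))
  if (!length(use)) stop("no known blocks supplied")
  out <- vector("list", length(use))
  names(out) <- use
  for (nm in use) {
    M <- unclass(new_blocks[[nm]])
    want <- names(bs$centers[[nm]])
    missing_vars <- setdiff(want, colnames(M))
    if (length(missing_vars))
      stop("block '", nm, "' is missing variable(s): ",
           paste(missing_vars, collapse = ", "))
    M <- M[, want, drop = FALSE]
    out[[nm]] <- sweep(sweep(M, 2, bs$centers[[nm]]), 2,
                       bs$scales[[nm]], "/")
  }
  out
}

#' Fully connected design matrix
#'
#' @param names block names.
#' @param value off-diagonal connection strength in \[0, 1\] (default 1).
#' @return Symmetric J x J matrix with zero diagonal.
#' @export
full_design <- function(names, value = 1) {
  J <- length(names)
  C <- matrix(value, J, J, dimnames = list(names, names))
  diag(C) <- 0
  C
}

check_design <- function(C, J, names) {
  C <- as.matrix(C)
  if (!all(dim(C) == J)) stop("design matrix must be ", J, " x ", J)
  if (max(abs(C - t(C))) > 1e-12) stop("design matrix must be symmetric")
  if (any(C < 0 | C > 1)) stop("design entries must lie in [0, 1]")
  if (any(diag(C) != 0)) stop("design diagonal must be zero")
  dimnames(C) <- list(names, names)
  C
}

#' Sparse generalized canonical correlation analysis
#'
#' Maximises the design-weighted sum of component covariances
#' \deqn{\sum_{i \ne h} c_{ih}\,\mathrm{cov}(X^{(i)} a^{(i)}, X^{(h)} a^{(h)})}
#' subject to \eqn{\|a^{(j)}\|_2 = 1} and a per-block cardinality constraint
#' (`keepX`, the operational form of the L1 shrinkage bound), by cyclic
#' block-coordinate ascent with soft-thresholding, for `D` dimensions with
#' regression deflation of each block between dimensions.
#'
#' For each block update the gradient direction is
#' \eqn{z^{(j)} = X^{(j)\top} \sum_{h \ne j} c_{jh} X^{(h)} a^{(h)}};
#' sparsity is enforced by truncating \eqn{z^{(j)}} to its keepX largest
#' absolute entries and renormalising to unit L2 norm. This truncation is
#' the exact maximiser of the block's coordinate step under the cardinality
#' constraint, so the objective is non-decreasing along the iterations
#' (`shrink = "soft"` instead shrinks the surviving entries by the
#' (keepX+1)-th largest magnitude, the classical L1-style proximal step,
#' whose varying effective L1 bound can let the unpenalised objective dip
#' between iterations). The
#' per-iteration trace is kept in the diagnostics. The sign convention makes
#' the largest-magnitude loading entry of each dimension positive, flipping
#' all blocks of that dimension together (a per-block flip could change the
#' sign of cross-block covariances and hence the achieved objective).
#'
#' @param bs a [block_set()].
#' @param C design matrix (default fully connected); see [full_design()].
#' @param keepX named list: for each block an integer vector (length `D`,
#'   recycled) of nonzero-loading counts; blocks omitted from the list are
#'   unpenalised.
#' @param D number of dimensions (components) to extract (default 2).
#' @param tol convergence threshold on the maximum absolute loading change
#'   (default `1e-6`).
#' @param max_iter inner iteration cap per dimension (default 100).
#' @param init `"svd"` (leading right singular vector per block,
#'   deterministic) or `"random"`.
#' @param shrink sparsity operator: `"hard"` (default, monotone ascent
#'   guaranteed) or `"soft"` (L1-style shrinkage of the survivors).
#' @param seed RNG seed used when `init = "random"`.
#' @return An object of class `sgcca_model`: per-block loading matrices
#'   (`loadings`, P_j x D, unit-norm sparse columns), component scores
#'   (`scores`, N x D), deflation projection vectors (`projections`),
#'   the design, keepX, centring/scaling parameters and convergence
#'   diagnostics (`iterations`, `objective`, `obj_trace`, `converged`).
#' @export
fit_sgcca <- function(bs, C = NULL, keepX = list(), D = 2, tol = 1e-6,
                      max_iter = 100, init = c("svd", "random"),
                      shrink = c("hard", "soft"), seed = 1) {
  stopifnot(inherits(bs, "block_set"))
  init <- match.arg(init)
  shrink <- match.arg(shrink)
  J <- length(bs$blocks)
  nms <- names(bs$blocks)
  if (is.null(C)) C <- full_design(nms)
  C <- check_design(C, J, nms)
  N <- length(bs$sample_ids)
  P <- vapply(bs$blocks, ncol, integer(1))
  kx <- matrix(rep(P, each = D), D, J, dimnames = list(NULL, nms))
  for (nm in names(keepX)) {
    if (!nm %in% nms) stop("keepX for unknown block: ", nm)
    v <- rep_len(as.integer(keepX[[nm]]), D)
    if (any(v < 1) || any(v > P[nm]))
      stop("keepX for block '", nm, "' out of range 1..", P[nm])
    kx[, nm] <- v
  }
  D_max <- min(N - 1, P)
  if (D < 1 || D > D_max)
    stop("D must lie in 1..", D_max, " for these blocks")
  if (init == "random") set.seed(seed)

  Xd <- lapply(bs$blocks, unclass)
  loadings <- lapply(P, function(p) matrix(0, p, D))
  for (j in seq_len(J)) rownames(loadings[[j]]) <- colnames(Xd[[j]])
  scores <- lapply(seq_len(J), function(j) matrix(0, N, D))
  projections <- lapply(P, function(p) matrix(0, D, p))
  iterations <- integer(D); converged <- logical(D)
  objective <- numeric(D); obj_trace <- vector("list", D)

  cov_obj <- function(s) {
    o <- 0
    for (i in seq_len(J)) for (h in seq_len(J)) if (i != h && C[i, h] > 0)
      o <- o + C[i, h] * sum(s[[i]] * s[[h]]) / (N - 1)
    o
  }

  for (d in seq_len(D)) {
    a <- vector("list", J)
    for (j in seq_len(J)) {
      a[[j]] <- if (init == "svd") {
        sv <- svd(Xd[[j]], nu = 0, nv = 1)
        drop(sv$v)
      } else {
        v <- stats::rnorm(P[j]); v / sqrt(sum(v^2))
      }
    }
    s <- lapply(seq_len(J), function(j) drop(Xd[[j]] %*% a[[j]]))
    trace <- cov_obj(s)
    it <- 0; ok <- FALSE
    while (it < max_iter) {
      it <- it + 1
      a_old <- a
      for (j in seq_len(J)) {
        inner <- numeric(N)
        for (h in seq_len(J)) if (h != j && C[j, h] > 0)
          inner <- inner + C[j, h] * s[[h]]
        z <- drop(crossprod(Xd[[j]], inner)) / (N - 1)
        k <- kx[d, j]
        if (k < P[j]) {
          if (shrink == "hard") {
            # exact maximiser of a'z under ||a||_2 = 1, ||a||_0 <= k:
            # keep the k largest |z| unshrunken (guarantees monotone ascent)
            drop_idx <- order(abs(z), decreasing = TRUE)[-seq_len(k)]
            z[drop_idx] <- 0
          } else {
            thr <- sort(abs(z), decreasing = TRUE)[k + 1]
            z <- sign(z) * pmax(abs(z) - thr, 0)
          }
        }
        nz <- sqrt(sum(z^2))
        if (nz > 0) a[[j]] <- z / nz  # else keep the previous direction
        s[[j]] <- drop(Xd[[j]] %*% a[[j]])
      }
      trace <- c(trace, cov_obj(s))
      delta <- max(vapply(seq_len(J),
                          function(j) max(abs(a[[j]] - a_old[[j]])),
                          numeric(1)))
      if (delta < tol) { ok <- TRUE; break }
    }
    if (!ok)
      warning("dimension ", d, " did not converge in ", max_iter,
              " iterations (recorded in diagnostics)")
    # sign convention: the largest-magnitude loading entry of the dimension
    # (across blocks) is positive; all blocks flip together so the achieved
    # objective is untouched
    all_a <- unlist(a)
    if (all_a[which.max(abs(all_a))] < 0)
      for (j in seq_len(J)) { a[[j]] <- -a[[j]]; s[[j]] <- -s[[j]] }
    for (j in seq_len(J)) {
      loadings[[j]][, d] <- a[[j]]
      scores[[j]][, d] <- s[[j]]
    }
    iterations[d] <- it; converged[d] <- ok
    objective[d] <- cov_obj(s); obj_trace[[d]] <- trace
    # regression deflation of every block by its own component
    for (j in seq_len(J)) {
      ss <- sum(s[[j]]^2)
      proj <- if (ss > 0) drop(crossprod(s[[j]], Xd[[j]])) / ss
      else numeric(P[j])
      projections[[j]][d, ] <- proj
      Xd[[j]] <- Xd[[j]] - tcrossprod(s[[j]], proj)
    }
  }
  names(loadings) <- names(scores) <- names(projections) <- nms
  structure(list(loadings = loadings, scores = scores,
                 projections = projections, design = C, keepX = kx,
                 centers = bs$centers, scales = bs$scales,
                 sample_ids = bs$sample_ids, blocks_scaled = bs$blocks,
                 D = D, tol = tol, max_iter = max_iter, init = init,
                 shrink = shrink,
                 iterations = iterations, converged = converged,
                 objective = objective, obj_trace = obj_trace),
            class = "sgcca_model")
}

#' @export
print.sgcca_model <- function(x, ...) {
  cat(sprintf("sgcca_model: %d block(s), %d dimension(s), N = %d\n",
              length(x$loadings), x$D, length(x$sample_ids)))
  for (nm in names(x$loadings))
    cat(sprintf("  %s: %d variables, keepX = %s\n", nm,
                nrow(x$loadings[[nm]]),
                paste(x$keepX[, nm], collapse = "/")))
  cat(sprintf("  objective per dimension: %s\n",
              paste(signif(x$objective, 4), collapse = ", ")))
  invisible(x)
}

#' Project new samples onto a fitted sGCCA model
#'
#' Applies the training centring/scaling, then reproduces the training
#' deflation sequence with the stored loadings and projection vectors to
#' obtain component scores for every block and dimension. Applied to the
#' training data it reproduces the stored scores.
#'
#' @param model an `sgcca_model`.
#' @param new_blocks named list of matrices carrying the training variable
#'   panels (extra columns are ignored; missing ones are an error).
#' @return Named list of N_new x D score matrices, one per block.
#' @export
sgcca_transform <- function(model, new_blocks) {
  stopifnot(inherits(model, "sgcca_model"))
  bs_stub <- structure(list(blocks = model$blocks_scaled,
                            centers = model$centers, scales = model$scales),
                       class = "block_set")
  Xd <- scale_like(bs_stub, new_blocks)
  out <- lapply(Xd, function(M)
    matrix(0, nrow(M), model$D,
           dimnames = list(rownames(M), paste0("comp", seq_len(model$D)))))
  for (d in seq_len(model$D)) {
    for (nm in names(out)) {
      s <- drop(Xd[[nm]] %*% model$loadings[[nm]][, d])
      out[[nm]][, d] <- s
      Xd[[nm]] <- Xd[[nm]] - tcrossprod(s, model$projections[[nm]][d, ])
    }
  }
  out
}

#' Rank the variables selected on a component
#'
#' Orders the nonzero-loading variables of one block and dimension by
#' absolute loading, most important first. When a group factor is supplied
#' (or stored by the supervised wrapper) each variable is annotated with
#' the class in which its training mean is higher — the colour code of the
#' usual loading plot.
#'
#' @param model an `sgcca_model` (or `diablo_model`).
#' @param block block name.
#' @param d dimension (default 1).
#' @param top how many variables to report (default 10); if fewer loadings
#'   are nonzero the list is truncated with a note attribute.
#' @param groups optional factor of training group labels.
#' @return data.frame `variable`, `loading`, `rank`, and `higher_in` when
#'   groups are known.
#' @export
rank_loadings <- function(model, block, d = 1, top = 10, groups = NULL) {
  if (inherits(model, "diablo_model") && is.null(groups))
    groups <- model$groups
  core <- if (inherits(model, "diablo_model")) model$model else model
  if (!block %in% names(core$loadings)) stop("unknown block: ", block)
  a <- core$loadings[[block]][, d]
  nz <- which(a != 0)
  ord <- nz[order(abs(a[nz]), decreasing = TRUE)]
  truncated <- top > length(ord)
  ord <- utils::head(ord, top)
  out <- data.frame(variable = names(a)[ord], loading = a[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    g <- droplevels(factor(groups))
    Xb <- core$blocks_scaled[[block]]
    out$higher_in <- vapply(out$variable, function(v) {
      m <- tapply(Xb[, v], g, mean)
      names(m)[which.max(m)]
    }, character(1))
  }
  if (truncated)
    attr(out, "note") <- sprintf(
      "requested top %d but only %d nonzero loadings", top, nrow(out))
  rownames(out) <- NULL
  out
}
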