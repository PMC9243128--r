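#' Dummy outcome block
#'
#' Encodes a two-or-more-level group factor as an N x (number of classes)
#' indicator matrix, to be centred/scaled like any other block so the
#' outcome can enter the sGCCA objective (the DIABLO construction).
#'
#' @param groups factor (or coercible) of class labels, >= 2 levels.
#' @param sample_ids row names.
#' @return Indicator matrix with one 1 per row before centring.
#' @export
outcome_block <- function(groups, sample_ids = names(groups)) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least two classes")
  Y <- stats::model.matrix(~ 0 + g)
  colnames(Y) <- levels(g)
  rownames(Y) <- sample_ids
  Y
}

#' Supervised multi-block discriminant model (DIABLO)
#'
#' Fits the sGCCA core with the dummy-coded outcome attached as an extra
#' block. The outcome block is never penalised; the design connects every
#' data block to the outcome with weight 1 and data blocks to each other
#' with `design_data` (default 1, the fully connected design).
#'
#' @param blocks named list of data-block matrices (shared sample order).
#' @param groups factor of class labels in the same sample order.
#' @param keepX named list of per-block keepX vectors (see [fit_sgcca()]).
#' @param D number of components (default 2).
#' @param design_data design weight among data blocks (default 1).
#' @param ... further arguments passed to [fit_sgcca()].
#' @return An object of class `diablo_model`: the underlying `sgcca_model`
#'   (`model`), the group factor, block names and per-block ensemble
#'   weights (average absolute correlation between each data block's
#'   components and the outcome components).
#' @export
fit_diablo <- function(blocks, groups, keepX = list(), D = 2,
                       design_data = 1, ...) {
  g <- droplevels(factor(groups))
  ids <- rownames(blocks[[1]])
  Y <- outcome_block(g, sample_ids = ids)
  all_blocks <- c(blocks, list(outcome = Y))
  bs <- block_set(all_blocks)
  J <- length(all_blocks)
  C <- full_design(names(all_blocks), value = design_data)
  C[, "outcome"] <- C["outcome", ] <- 1
  diag(C) <- 0
  model <- fit_sgcca(bs, C = C, keepX = keepX, D = D, ...)
  dn <- setdiff(names(all_blocks), "outcome")
  w <- vapply(dn, function(nm) {
    mean(vapply(seq_len(model$D), function(d)
      abs(stats::cor(model$scores[[nm]][, d],
                     model$scores[["outcome"]][, d])), numeric(1)))
  }, numeric(1))
  structure(list(model = model, groups = g, data_blocks = dn, weights = w),
            class = "diablo_model")
}

#' @export
print.diablo_model <- function(x, ...) {
  cat(sprintf("diablo_model: %s vs %s (n = %s), blocks: %s\n",
              levels(x$groups)[1], levels(x$groups)[2],
              paste(table(x$groups), collapse = "/"),
              paste(x$data_blocks, collapse = ", ")))
  print(x$model)
  invisible(x)
}

#' Stratified train/test split
#'
#' @param groups factor of class labels (named by sample id, or supply a
#'   [sample_metadata()] data.frame).
#' @param fraction training proportion (default 0.8).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(groups, fraction = 0.8, seed = 1) {
  if (inherits(groups, "sample_metadata")) {
    g <- factor(groups$group)
  } else g <- factor(groups)
  if (any(table(g) < 5)) stop("need at least 5 samples per class to split")
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(g)) {
    idx <- which(g == lv)
    n_tr <- round(fraction * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(g), train))
}

#' Predict class membership for new samples
#'
#' Computes component scores for every data block via the stored model,
#' then assigns classes per block and combines blocks by a weighted vote
#' (weights = the model's block-outcome component correlations).
#'
#' Distances: `"centroid-dist"` (default) assigns the nearest class
#' centroid in the block's component space; `"mahalanobis-dist"` uses the
#' pooled within-class covariance of the training scores;
#' `"max-dist"` regresses the outcome indicators on the training scores and
#' assigns the class with the largest predicted indicator.
#'
#' @param object a `diablo_model`.
#' @param new_blocks named list of data-block matrices.
#' @param distance prediction distance (see above).
#' @param ... unused.
#' @return A list of class `diablo_prediction`: per-block class calls
#'   (`block_class`), ensemble calls (`class`), per-block score arrays
#'   (`scores`) and the vote weights.
#' @export
predict.diablo_model <- function(object, new_blocks,
                                 distance = c("centroid-dist",
                                              "mahalanobis-dist",
                                              "max-dist"), ...) {
  distance <- match.arg(distance)
  core <- object$model
  g <- object$groups
  lv <- levels(g)
  sc_new <- sgcca_transform(core, new_blocks)
  dn <- intersect(object$data_blocks, names(new_blocks))
  if (!length(dn)) stop("no known data blocks supplied")
  n_new <- nrow(sc_new[[dn[1]]])
  block_class <- matrix(NA_character_, n_new, length(dn),
                        dimnames = list(NULL, dn))
  for (nm in dn) {
    tr <- core$scores[[nm]]
    te <- sc_new[[nm]]
    if (distance == "max-dist") {
      Y <- outcome_block(g, sample_ids = core$sample_ids)
      B <- solve(crossprod(tr), crossprod(tr, Y))
      pred <- te %*% B
      block_class[, nm] <- lv[apply(pred, 1, which.max)]
    } else {
      centroids <- do.call(rbind, lapply(lv, function(cl)
        colMeans(tr[g == cl, , drop = FALSE])))
      W <- diag(ncol(tr))
      if (distance == "mahalanobis-dist") {
        S <- Reduce(`+`, lapply(lv, function(cl) {
          M <- tr[g == cl, , drop = FALSE]
          crossprod(sweep(M, 2, colMeans(M)))
        })) / (nrow(tr) - length(lv))
        W <- solve(S)
      }
      dists <- vapply(seq_along(lv), function(k) {
        delta <- sweep(te, 2, centroids[k, ])
        rowSums((delta %*% W) * delta)
      }, numeric(n_new))
      block_class[, nm] <- lv[apply(matrix(dists, nrow = n_new), 1,
                                    which.min)]
    }
  }
  w <- object$weights[dn]
  ensemble <- vapply(seq_len(n_new), function(i) {
    votes <- tapply(w, factor(block_class[i, ], levels = lv), sum,
                    default = 0)
    lv[which.max(votes)]
  }, character(1))
  structure(list(class = factor(ensemble, levels = lv),
                 block_class = block_class, scores = sc_new,
                 weights = w, distance = distance),
            class = "diablo_prediction")
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic with average
#' ranks (tie-corrected): the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or two-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted DIABLO model on given samples
#'
#' The per-sample score is the ensemble-weighted difference of
#' distances to the two class centroids on component 1 (positive when the
#' sample sits closer to the second class level), the default score
#' definition for the model's ROC summaries.
#'
#' @param object a `diablo_model`.
#' @param new_blocks data blocks for the scored samples.
#' @param labels true class labels of those samples.
#' @return AUC in \[0, 1\].
#' @export
diablo_auc <- function(object, new_blocks, labels) {
  core <- object$model
  g <- object$groups
  lv <- levels(g)
  sc_new <- sgcca_transform(core, new_blocks)
  dn <- intersect(object$data_blocks, names(new_blocks))
  w <- object$weights[dn]; w <- w / sum(w)
  score <- 0
  for (nm in dn) {
    tr <- core$scores[[nm]][, 1]
    c1 <- mean(tr[g == lv[1]]); c2 <- mean(tr[g == lv[2]])
    s <- sc_new[[nm]][, 1]
    score <- score + w[[nm]] * (abs(s - c1) - abs(s - c2))
  }
  auc(score, factor(labels, levels = lv))
}

#' Stratified K-fold cross-validation of the DIABLO classifier
#'
#' Repeated stratified K-fold CV reporting per-fold and mean balanced
#' error rates; optionally tunes keepX for one block over a grid,
#' minimising mean balanced error with ties broken toward the smaller
#' keepX.
#'
#' @param blocks named list of data-block matrices.
#' @param groups factor of class labels.
#' @param folds K (default 5); must not exceed the smallest class.
#' @param repeats number of CV repetitions (default 1).
#' @param seed RNG seed for fold assignment.
#' @param keepX fixed keepX list passed to [fit_diablo()].
#' @param keepX_grid optional list `(block = <name>, values = <integers>)`;
#'   when supplied the CV is run per grid value.
#' @param D,distance,design_data passed through.
#' @return List with `balanced_error` (mean), `fold_errors`, `folds`
#'   (assignment per sample per repeat), and when tuning: `chosen_keepX`
#'   and the per-value `grid_errors`.
#' @export
cross_validate <- function(blocks, groups, folds = 5, repeats = 1, seed = 1,
                           keepX = list(), keepX_grid = NULL, D = 2,
                           distance = "centroid-dist", design_data = 1) {
  g <- droplevels(factor(groups))
  if (folds < 2) stop("folds must be >= 2")
  loo <- folds == length(g)   # leave-one-out: stratification is vacuous
  if (!loo && folds > min(table(g)))
    stop("folds exceed the smallest class size")
  run_cv <- function(kx) {
    set.seed(seed)
    errs <- c(); assign_log <- list()
    for (r in seq_len(repeats)) {
      fold_of <- integer(length(g))
      if (loo) {
        fold_of <- seq_along(g)
      } else for (lv in levels(g)) {
        idx <- which(g == lv)
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))[sample(length(idx))]
      }
      assign_log[[r]] <- fold_of
      for (f in seq_len(folds)) {
        te <- which(fold_of == f); tr <- which(fold_of != f)
        fit <- fit_diablo(lapply(blocks, function(b)
          b[tr, , drop = FALSE]), g[tr], keepX = kx, D = D,
          design_data = design_data)
        pred <- predict(fit, lapply(blocks, function(b)
          b[te, , drop = FALSE]), distance = distance)
        per_class <- vapply(levels(g), function(lv2) {
          sel <- g[te] == lv2
          if (!any(sel)) return(NA_real_)
          mean(pred$class[sel] != lv2)
        }, numeric(1))
        errs <- c(errs, mean(per_class, na.rm = TRUE))
      }
    }
    list(mean = mean(errs), fold = errs, folds = assign_log)
  }
  if (is.null(keepX_grid)) {
    cv <- run_cv(keepX)
    return(list(balanced_error = cv$mean, fold_errors = cv$fold,
                folds = cv$folds))
  }
  blk <- keepX_grid$block; vals <- sort(keepX_grid$values)
  grid_err <- vapply(vals, function(v) {
    kx <- keepX; kx[[blk]] <- v
    run_cv(kx)$mean
  }, numeric(1))
  best <- vals[which.min(grid_err)]  # ties -> smallest keepX (sorted)
  kx <- keepX; kx[[blk]] <- best
  cv <- run_cv(kx)
  list(balanced_error = cv$mean, fold_errors = cv$fold, folds = cv$folds,
       chosen_keepX = best, grid_errors = stats::setNames(grid_err, vals))
}
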