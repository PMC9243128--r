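# Independent oracle implementations used across the suite. These stay
# deliberately naive (brute force / textbook formulas) and never call the
# package functions they check.

# Random compositional peak matrix closed to 100.
random_peak_matrix <- function(n, p = 39, seed = 1) {
  set.seed(seed)
  A <- matrix(exp(rnorm(n * p)), n, p)
  A <- 100 * A / rowSums(A)
  glycan_matrix(A, sample_ids = sprintf("s%02d", seq_len(n)),
                peak_ids = default_peak_panel(p), tol = 1e-9)
}

meta_for <- function(X, group = "control", batch = "b1") {
  sample_metadata(data.frame(sample_id = rownames(X),
                             group = rep_len(group, nrow(X)),
                             batch = rep_len(batch, nrow(X)),
                             stringsAsFactors = FALSE))
}

# Naive O(n^3) Ward clustering: Lance-Williams update on squared Euclidean
# distances, heights reported on the distance (sqrt) scale.
naive_ward <- function(X) {
  D2 <- as.matrix(dist(X))^2
  n <- nrow(D2)
  active <- seq_len(n); sizes <- rep(1, n); id <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2); heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, 0, 0)
    m <- length(active)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      d <- D2[active[i], active[j]]
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- active[best[2]]; j <- active[best[3]]
    merges[step, ] <- sort(c(id[i], id[j]))
    heights[step] <- sqrt(best[1])
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj; id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# hclust merge rows as unordered sorted pairs, for comparison with the oracle.
sorted_merges <- function(hc) t(apply(hc$merge, 1, sort))

# Brute-force exact two-tailed Mann-Whitney p over all label assignments.
brute_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y), ties.method = "average")
  stat <- function(sel) abs(sum(r[sel]) - n1 * (length(sel) + 1) / 2 -
                              n1 * (n - n1) / 2)
  obs <- stat(seq_len(n1))
  combs <- utils::combn(n, n1)
  mean(apply(combs, 2, stat) >= obs - 1e-9)
}

# Brute-force component-mediated similarity from its definition.
brute_similarity <- function(model, bi, bh, D_use = 1) {
  core <- if (inherits(model, "diablo_model")) model$model else model
  Xi <- core$blocks_scaled[[bi]]; Xh <- core$blocks_scaled[[bh]]
  S <- matrix(0, ncol(Xi), ncol(Xh))
  for (d in seq_len(D_use)) {
    z <- (core$scores[[bi]][, d] + core$scores[[bh]][, d]) / 2
    for (p in seq_len(ncol(Xi))) for (q in seq_len(ncol(Xh)))
      S[p, q] <- S[p, q] + cor(Xi[, p], z) * cor(Xh[, q], z)
  }
  pmin(pmax(S, -1), 1)
}

# Small prepared two-block set from seeded Gaussians.
toy_block_set <- function(n = 20, p1 = 4, p2 = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  X1 <- matrix(rnorm(n * p1), n, p1,
               dimnames = list(ids, paste0("a", seq_len(p1))))
  X2 <- matrix(rnorm(n * p2), n, p2,
               dimnames = list(ids, paste0("b", seq_len(p2))))
  block_set(list(A = X1, B = X2))
}
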