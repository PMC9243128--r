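#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c contingency table, no continuity
#' correction, with df = (r-1)(c-1) and an upper-tail chi-square p-value.
#'
#' @param tab r x c matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @param feature_id optional label carried into the result.
#' @return A one-row data.frame of class `univariate_result` with
#'   `feature_id`, `test`, `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(tab, feature_id = NA_character_) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  univariate_result(feature_id, "chi-square", unname(ct$statistic),
                    unname(ct$parameter), ct$p.value)
}

#' Two-sample t test
#'
#' Pooled-variance Student's t by default; Welch available. Two degenerate
#' cases are fixed by contract: both groups constant and equal gives t = 0,
#' p = 1; both constant but different is an error (the statistic is
#' undefined).
#'
#' @param x,y numeric vectors, each with at least 2 observations.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param feature_id optional label.
#' @return A `univariate_result` row (two-tailed p) plus group mean/SD
#'   columns.
#' @export
students_t <- function(x, y, variant = c("pooled", "welch"),
                       feature_id = NA_character_) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (x[1] == y[1]) {
      res <- univariate_result(feature_id, "student-t", 0,
                               length(x) + length(y) - 2, 1)
    } else {
      stop("zero variance in both groups with unequal means: ",
           "t statistic undefined")
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    res <- univariate_result(feature_id, "student-t", unname(tt$statistic),
                             unname(tt$parameter), tt$p.value)
  }
  res$mean_x <- mean(x); res$sd_x <- stats::sd(x)
  res$mean_y <- mean(y); res$sd_y <- stats::sd(y)
  res
}

#' Mann-Whitney U test
#'
#' Reports the min-convention U statistic. The two-tailed p-value uses the
#' exact permutation distribution of U (enumeration of all label
#' assignments, valid under ties) when the smaller group has fewer than 8
#' observations and the enumeration is tractable; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (n1, n2 >= 1).
#' @param exact force (`TRUE`)/forbid (`FALSE`) exact enumeration; default
#'   `NULL` picks by the min(n) < 8 rule.
#' @param feature_id optional label.
#' @return A `univariate_result` row with `statistic` = min(U1, U2).
#' @export
mann_whitney_u <- function(x, y, exact = NULL, feature_id = NA_character_) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (is.null(exact))
    exact <- min(n1, n2) < 8 && choose(n1 + n2, n1) <= 2e5
  if (exact) {
    p <- mw_exact_p(r, n1)
  } else {
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {  # everything tied
      p <- 1
    } else {
      z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  univariate_result(feature_id, "mann-whitney-u", U, NA_real_, p)
}

# Exact two-tailed p for the Mann-Whitney U by full enumeration of the
# C(n1+n2, n1) label assignments on the observed (tied) ranks.
mw_exact_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  combs <- utils::combn(n, n1)
  U1s <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  dev <- abs(U1s - n1 * n2 / 2)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - n1 * n2 / 2)
  mean(dev >= obs - 1e-9)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: \eqn{q_i = \min_{j \ge i} p_{(j)} m / j}, reported
#' in the original input order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Vector of q-values, same order and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS distance of the sample against a normal with the sample mean and SD.
#' Because the parameters are estimated from the same data, the asymptotic
#' p-value is anti-conservative and is flagged as approximate; it is used
#' here only as a screening diagnostic (with QQ plots) for choosing between
#' t and rank tests.
#'
#' @param x numeric vector, n >= 5, non-constant.
#' @param feature_id optional label.
#' @return A `univariate_result` row with an `approximate = TRUE` column.
#' @export
ks_normality <- function(x, feature_id = NA_character_) {
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant vector: KS statistic undefined")
  kt <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  res <- univariate_result(feature_id, "ks-normality", unname(kt$statistic),
                           NA_real_, kt$p.value)
  res$approximate <- TRUE
  res
}

univariate_result <- function(feature_id, test, statistic, df, p) {
  structure(data.frame(feature_id = feature_id, test = test,
                       statistic = statistic, df = df, p = p,
                       stringsAsFactors = FALSE),
            class = c("univariate_result", "data.frame"))
}

#' Screen features for group differences
#'
#' Per-feature Mann-Whitney tests between the two groups, BH adjustment
#' over the whole feature family, and per-cluster K (cluster size) / k
#' (members significant at `alpha` on raw p) counts when a cluster
#' assignment is supplied.
#'
#' @param X samples x features matrix (any scale).
#' @param meta [sample_metadata()] with a two-level `group`.
#' @param alpha significance level for the cluster counts (default 0.05).
#' @param clusters optional named vector of cluster labels per feature.
#' @return List with `results` (per-feature data.frame including `q`) and
#'   `clusters` (per-cluster summary data.frame, NULL when no assignment).
#' @export
screen_features <- function(X, meta, alpha = 0.05, clusters = NULL) {
  meta <- align_metadata(X, meta)
  g <- assert_two_groups(meta)
  M <- unclass(X)
  rows <- lapply(colnames(M), function(f)
    mann_whitney_u(M[g == levels(g)[1], f], M[g == levels(g)[2], f],
                   feature_id = f))
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  cl <- NULL
  if (!is.null(clusters)) {
    unknown <- setdiff(names(clusters), colnames(M))
    if (length(unknown))
      stop("cluster assignment for unknown feature(s): ",
           paste(unknown, collapse = ", "))
    cluster_ids <- if (is.factor(clusters)) levels(clusters)
    else sort(unique(clusters))   # factor levels admit empty clusters
    cl <- do.call(rbind, lapply(cluster_ids, function(cid) {
      members <- names(clusters)[clusters == cid]
      pk <- res$p[match(members, res$feature_id)]
      data.frame(cluster_id = cid, K = length(members),
                 k = sum(pk < alpha),
                 members = paste(members, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(results = res, clusters = cl)
}
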