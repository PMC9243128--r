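#' Empirical-Bayes batch correction (parametric ComBat)
#'
#' Location/scale batch adjustment with parametric empirical-Bayes
#' shrinkage. Each feature is standardised against its grand mean (with the
#' group effect optionally kept in the mean model so biological signal is
#' not absorbed into batch estimates) and pooled variance; per-batch
#' location (\eqn{\hat\gamma}) and scale (\eqn{\hat\delta^2}) estimates are
#' shrunk toward batch-level normal / inverse-gamma priors fitted by the
#' method of moments, iterating the coupled location/scale updates to a
#' fixed point; the data are then back-transformed.
#'
#' With a single batch there is nothing to correct: the input is returned
#' unchanged with \eqn{\gamma^* = 0}, \eqn{\delta^{2*} = 1}.
#'
#' @param X a [glycan_matrix()] (samples x features); the batch model works
#'   on whatever scale `X` is on (for compositional UPLC percentages the
#'   plate artefact is approximately location/scale on this scale after the
#'   generator's log-scale artefacts of moderate size).
#' @param meta [sample_metadata()] carrying the `batch` factor (and `group`
#'   when `preserve_group = TRUE`).
#' @param preserve_group keep the two-group effect in the mean model
#'   (default `TRUE`).
#' @param eb apply empirical-Bayes shrinkage (default `TRUE`); with
#'   `eb = FALSE` the raw per-batch location/scale standardisation is used
#'   (exactly idempotent, and the large-sample limit of the EB variant).
#' @param conv fixed-point tolerance of the EB iteration (default `1e-6`).
#' @return A list with `corrected` (a non-compositional [glycan_matrix()])
#'   and `model` (class `batch_model`: `gamma_hat`, `gamma_star`,
#'   `delta2_hat`, `delta2_star` — batches x features — plus the prior
#'   hyperparameters `gamma_bar`, `tau2`, `a_prior`, `b_prior` per batch,
#'   the pooled variance and the standardisation mean).
#' @export
combat_correct <- function(X, meta, preserve_group = TRUE, eb = TRUE,
                           conv = 1e-6) {
  meta <- align_metadata(X, meta)
  batch <- droplevels(factor(meta$batch))
  M <- unclass(X)
  n <- nrow(M); p <- ncol(M)
  feat_var <- apply(M, 2, stats::var)
  if (any(feat_var == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(M)[feat_var == 0], collapse = ", "))
  nb <- table(batch)
  if (any(nb < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  I <- nlevels(batch)
  if (I == 1L) {
    zero <- matrix(0, 1, p, dimnames = list(levels(batch), colnames(M)))
    model <- structure(list(gamma_hat = zero, gamma_star = zero,
                            delta2_hat = zero + 1, delta2_star = zero + 1,
                            gamma_bar = 0, tau2 = NA_real_,
                            a_prior = NA_real_, b_prior = NA_real_,
                            var_pooled = feat_var,
                            stand_mean = colMeans(M), batches = levels(batch)),
                       class = "batch_model")
    return(list(corrected = rewrap(M, X, compositional = FALSE),
                model = model))
  }
  B <- stats::model.matrix(~ 0 + batch)              # n x I indicators
  D <- B
  if (isTRUE(preserve_group)) {
    g <- droplevels(factor(meta$group))
    if (nlevels(g) > 1L)
      D <- cbind(B, stats::model.matrix(~ g)[, -1, drop = FALSE])
  }
  # per-feature OLS for batch + preserved covariates
  beta <- solve(crossprod(D), crossprod(D, M))       # (I+q) x p
  grand <- as.numeric(nb / n) %*% beta[seq_len(I), , drop = FALSE]  # 1 x p
  stand_mean <- matrix(grand, n, p, byrow = TRUE)
  if (ncol(D) > I)
    stand_mean <- stand_mean +
      D[, -seq_len(I), drop = FALSE] %*% beta[-seq_len(I), , drop = FALSE]
  resid <- M - D %*% beta
  var_pooled <- colSums(resid^2) / n
  Z <- (M - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- delta2_hat <- matrix(NA_real_, I, p,
                                    dimnames = list(levels(batch), colnames(M)))
  for (i in seq_len(I)) {
    rows <- batch == levels(batch)[i]
    gamma_hat[i, ] <- colMeans(Z[rows, , drop = FALSE])
    delta2_hat[i, ] <- apply(Z[rows, , drop = FALSE], 2, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta2_hat)
  s2_d <- apply(delta2_hat, 1, stats::var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_len(I)) {
    rows <- batch == levels(batch)[i]
    ni <- sum(rows)
    Zi <- Z[rows, , drop = FALSE]
    g_new <- gamma_hat[i, ]; d_new <- delta2_hat[i, ]
    if (isTRUE(eb)) repeat {
      g_old <- g_new; d_old <- d_new
      g_new <- (ni * tau2[i] * gamma_hat[i, ] + d_new * gamma_bar[i]) /
        (ni * tau2[i] + d_new)
      ss <- colSums((Zi - matrix(g_new, ni, p, byrow = TRUE))^2)
      d_new <- (b_prior[i] + 0.5 * ss) / (ni / 2 + a_prior[i] - 1)
      if (max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
              abs(d_new - d_old) / pmax(abs(d_old), 1e-12)) < conv) break
    }
    gamma_star[i, ] <- g_new
    delta2_star[i, ] <- d_new
    Z[rows, ] <- (Zi - matrix(g_new, ni, p, byrow = TRUE)) /
      matrix(sqrt(d_new), ni, p, byrow = TRUE)
  }
  corrected <- Z * matrix(sqrt(var_pooled), n, p, byrow = TRUE) + stand_mean
  model <- structure(list(gamma_hat = gamma_hat, gamma_star = gamma_star,
                          delta2_hat = delta2_hat, delta2_star = delta2_star,
                          gamma_bar = gamma_bar, tau2 = tau2,
                          a_prior = a_prior, b_prior = b_prior,
                          var_pooled = var_pooled,
                          stand_mean = stand_mean[1, ],
                          batches = levels(batch)),
                     class = "batch_model")
  list(corrected = rewrap(corrected, X, compositional = FALSE), model = model)
}
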