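# log-scale Gaussian feature table with a planted batch structure; shift
# and scale are recycled over features, so vectors plant heterogeneous
# (feature-specific) batch effects
log_scale_fixture <- function(n_per = 50, p = 39, shift = 1, scale = 1,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rnorm(n * p, mean = rep(seq(2, -1, length.out = p), each = n),
                    sd = 0.35), n, p)
  b <- rep(c("b1", "b2"), each = n_per)
  shift <- rep_len(shift, p); scale <- rep_len(scale, p)
  X[b == "b2", ] <- sweep(sweep(X[b == "b2", ], 2, scale, "*"), 2,
                          shift, "+")
  gm <- glycan_matrix(X, sample_ids = sprintf("s%03d", seq_len(n)),
                      peak_ids = default_peak_panel(p),
                      compositional = FALSE)
  list(X = gm, meta = meta_for(gm, batch = b))
}

test_that("batch correction is the identity for a single batch", {
  X <- random_peak_matrix(10, seed = 6)
  cc <- combat_correct(X, meta_for(X))
  expect_equal(unclass(cc$corrected), unclass(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(max(abs(cc$model$gamma_star)), 0)
  expect_equal(max(abs(cc$model$delta2_star - 1)), 0)
  expect_false(attr(cc$corrected, "compositional"))
})

test_that("a planted unit batch shift is removed to <0.05 mean residual", {
  fx <- log_scale_fixture(shift = 1, seed = 9)
  cc <- combat_correct(fx$X, fx$meta, preserve_group = FALSE)
  M <- unclass(cc$corrected)
  b <- fx$meta$batch
  md <- colMeans(M[b == "b1", ]) - colMeans(M[b == "b2", ])
  expect_lt(mean(abs(md)), 0.05)
  expect_true(all(cc$model$delta2_star > 0))
})

test_that("empirical-Bayes estimates agree with sva::ComBat", {
  fx <- log_scale_fixture(n_per = 40, p = 20, shift = 0.7, scale = 1.4,
                          seed = 11)
  meta <- fx$meta
  meta$group <- rep_len(c("control", "case"), nrow(fx$X))
  mine <- combat_correct(fx$X, meta, preserve_group = TRUE)
  ref <- t(sva::ComBat(dat = t(unclass(fx$X)), batch = meta$batch,
                       mod = model.matrix(~ factor(meta$group)),
                       par.prior = TRUE))
  expect_lt(max(abs(unclass(mine$corrected) - ref)), 1e-4)
})

test_that("EB shrinkage approaches the plain standardisation for large batches", {
  # heterogeneous per-feature batch effects keep the EB priors diffuse;
  # shrinkage must then vanish at rate ~1/n per batch
  dev <- vapply(c(500, 2000), function(nper) {
    fx <- log_scale_fixture(n_per = nper, p = 39,
                            shift = seq(-1, 1, length.out = 39),
                            scale = seq(1.05, 1.6, length.out = 39),
                            seed = 10)
    eb <- combat_correct(fx$X, fx$meta, preserve_group = FALSE)
    raw <- combat_correct(fx$X, fx$meta, preserve_group = FALSE, eb = FALSE)
    c(gamma = max(abs(eb$model$gamma_star - raw$model$gamma_star)),
      cell = max(abs(unclass(eb$corrected) - unclass(raw$corrected)) /
                   pmax(abs(unclass(raw$corrected)), 1)))
  }, numeric(2))
  # location estimates agree within 2% already at n = 500 per batch
  expect_lt(dev["gamma", 1], 0.02)
  expect_lt(dev["cell", 1], 0.05)
  # quadrupling n cuts the worst-case deviations by well over half
  expect_lt(dev["gamma", 2], dev["gamma", 1] / 2)
  expect_lt(dev["cell", 2], dev["cell", 1] / 2)

  # the no-shrinkage variant equalises batch means exactly
  fx <- log_scale_fixture(n_per = 100, seed = 10)
  raw <- combat_correct(fx$X, fx$meta, preserve_group = FALSE, eb = FALSE)
  M <- unclass(raw$corrected); b <- fx$meta$batch
  expect_lt(max(abs(colMeans(M[b == "b1", ]) - colMeans(M[b == "b2", ]))),
            1e-8)
})

test_that("a second correction pass changes far less than the first", {
  fx <- log_scale_fixture(shift = 1, seed = 12)
  c1 <- combat_correct(fx$X, fx$meta, preserve_group = FALSE)
  c2 <- combat_correct(c1$corrected, fx$meta, preserve_group = FALSE)
  first <- max(abs(unclass(c1$corrected) - unclass(fx$X)))
  second <- max(abs(unclass(c2$corrected) - unclass(c1$corrected)))
  expect_lt(second, 0.2 * first)
})

test_that("batch correction rejects degenerate designs", {
  X <- random_peak_matrix(5, seed = 7)
  meta <- meta_for(X, batch = c("b1", "b1", "b1", "b1", "b2"))
  expect_error(combat_correct(X, meta), "b2")
  Xc <- unclass(random_peak_matrix(6, seed = 8))
  Xc[, 3] <- 1
  gm <- glycan_matrix(Xc, rownames(Xc), colnames(Xc), compositional = FALSE)
  expect_error(combat_correct(gm, meta_for(gm, batch = rep(c("b1", "b2"), 3))),
               "GP3")
})

test_that("median quotient normalisation recovers planted dilutions", {
  # eight dilutions of one base spectrum: factors are exactly the dilution
  # coefficients relative to their median
  base <- unclass(random_peak_matrix(1, seed = 13))[1, ]
  coef <- c(1, 1, 3, 1, 1, 1, 1, 1)   # sample 3 is 3x more concentrated
  M <- outer(coef, base)
  dimnames(M) <- list(sprintf("s%02d", 1:8), names(base))
  gm <- glycan_matrix(M, rownames(M), colnames(M), compositional = FALSE)
  qn <- median_quotient_normalize(gm)
  expect_equal(unname(qn$factors), coef, tolerance = 1e-12)
  expect_equal(unclass(qn$normalized)[3, ], base, tolerance = 1e-9)

  # identical samples: every factor 1, data unchanged
  same <- glycan_matrix(outer(rep(1, 4), base), sprintf("t%d", 1:4),
                        names(base), compositional = FALSE)
  qs <- median_quotient_normalize(same)
  expect_equal(unname(qs$factors), rep(1, 4))
  expect_equal(unclass(qs$normalized), unclass(same))

  # invariant: per-sample median quotient against the reference is 1
  ref <- apply(unclass(qn$normalized), 2, median)
  mq <- apply(unclass(qn$normalized), 1, function(r) median(r / ref))
  expect_equal(unname(mq), rep(1, 8), tolerance = 1e-9)

  # single sample with itself as reference
  one <- glycan_matrix(M[1, , drop = FALSE], "s01", colnames(M),
                       compositional = FALSE)
  expect_equal(unname(median_quotient_normalize(one, reference = "s01")$factors),
               1)
  # zero entries are named and rejected
  M[2, 5] <- 0
  gm0 <- glycan_matrix(M, rownames(M), colnames(M), compositional = FALSE)
  expect_error(median_quotient_normalize(gm0), "GP5")
})

test_that("rank transform follows the average-rank and Blom conventions", {
  v <- glycan_matrix(cbind(GP1 = c(3, 1, 7, 5, 9), GP2 = c(2, 2, 5, 1, 3)),
                     sample_ids = paste0("s", 1:5), compositional = FALSE)
  r <- rank_transform(v)
  expect_equal(unname(unclass(r)[, "GP1"]), c(2, 1, 4, 3, 5))
  expect_equal(unname(unclass(r)[, "GP2"])[1:3], c(2.5, 2.5, 5))
  expect_false(attr(r, "compositional"))

  tie <- glycan_matrix(cbind(GP1 = c(2, 2, 5)), paste0("s", 1:3),
                       compositional = FALSE)
  expect_equal(unname(unclass(rank_transform(tie))[, 1]), c(1.5, 1.5, 3))

  x <- glycan_matrix(cbind(GP1 = sample(101)), paste0("s", 1:101),
                     compositional = FALSE)
  inv <- unclass(rank_transform(x, mode = "inverse-normal"))[, 1]
  expect_equal(sort(unname(inv)), sort(unname(-inv)),
               tolerance = 1e-12)   # symmetric about 0
  expect_equal(max(inv), qnorm((101 - 3 / 8) / (101 + 1 / 4)),
               tolerance = 1e-12)

  const <- glycan_matrix(cbind(GP1 = rep(2, 6)), paste0("s", 1:6),
                         compositional = FALSE)
  expect_error(rank_transform(const, mode = "inverse-normal"), "constant")
})

test_that("rank transform is invariant to monotone per-feature maps", {
  X <- random_peak_matrix(15, seed = 14)
  r1 <- rank_transform(X)
  M <- unclass(X)
  M[, 1] <- exp(M[, 1]); M[, 2] <- M[, 2]^3; M[, 3] <- 10 * M[, 3] + 2
  gm <- glycan_matrix(M, rownames(M), colnames(M), compositional = FALSE)
  expect_equal(unclass(rank_transform(gm)), unclass(r1))
})

test_that("PCA flags a planted plate artefact and clears after correction", {
  # a strong plate artefact is always visible on component 1
  before_p <- vapply(1:5, function(s) {
    sim <- simulate_glycome(simulation_config(
      n_control = 50, n_case = 50, effect_size = 0, n_batches = 2,
      batch_shift = c(0, 1), batch_scale = 1, seed = s))
    pca_batch_check(sim$peaks, sim$meta)$p[1]
  }, numeric(1))
  expect_true(all(before_p < 0.001))
  # after correction of a moderate artefact the association clears
  after_p <- vapply(1:20, function(s) {
    sim <- simulate_glycome(simulation_config(
      n_control = 50, n_case = 50, effect_size = 0, n_batches = 2,
      batch_shift = c(0, 0.5), batch_scale = 1, seed = s))
    cc <- combat_correct(sim$peaks, sim$meta)
    pca_batch_check(cc$corrected, sim$meta)$p[1]
  }, numeric(1))
  expect_gte(sum(after_p > 0.05), 18)
})

test_that("PCA batch association is null when plates are unrelated to data", {
  p <- vapply(1:40, function(s) {
    X <- random_peak_matrix(30, seed = 100 + s)
    set.seed(200 + s)
    meta <- meta_for(X, batch = sample(rep(c("b1", "b2", "b3"), each = 10)))
    pca_batch_check(X, meta)$p[1]
  }, numeric(1))
  # roughly uniform: KS at desk scale
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
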