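test_that("block sets are centred, scaled and order-checked", {
  bs <- toy_block_set(seed = 80)
  for (b in bs$blocks) {
    expect_lt(max(abs(colMeans(b))), 1e-8)
    expect_equal(unname(apply(b, 2, sd)), rep(1, ncol(b)), tolerance = 1e-8)
  }
  X1 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), c("a", "b")))
  X2 <- X1[5:1, ]
  expect_error(block_set(list(A = X1, B = X2)), "sample order")
  X1[, 1] <- 1
  expect_error(block_set(list(A = X1)), "constant")
})

test_that("two single-variable identical blocks give the forced solution", {
  set.seed(81)
  x <- rnorm(12)
  ids <- paste0("s", 1:12)
  bs <- block_set(list(A = matrix(x, dimnames = list(ids, "x")),
                       B = matrix(x, dimnames = list(ids, "y"))))
  m <- fit_sgcca(bs, D = 1)
  expect_equal(unname(m$loadings$A[, 1]), 1)
  expect_equal(unname(m$loadings$B[, 1]), 1)
  # objective = 2 * cov of the standardized variable with itself = 2
  expect_equal(m$objective, 2, tolerance = 1e-8)
})

test_that("unsparse two-block fits equal the cross-covariance SVD", {
  for (s in 1:25) {
    bs <- toy_block_set(n = 20, p1 = 4, p2 = 3, seed = s)
    m <- fit_sgcca(bs, D = 1, tol = 1e-10, max_iter = 2000)
    sv <- svd(crossprod(bs$blocks$A, bs$blocks$B) / 19)
    expect_lt(max(abs(abs(m$loadings$A[, 1]) - abs(sv$u[, 1]))), 1e-6)
    expect_lt(max(abs(abs(m$loadings$B[, 1]) - abs(sv$v[, 1]))), 1e-6)
    expect_equal(m$objective, 2 * sv$d[1], tolerance = 1e-8)
  }
})

test_that("the optimizer reaches the exhaustive grid maximum (P = 2)", {
  th1 <- seq(0, 180, by = 0.1) * pi / 180
  th2 <- seq(0, 360, by = 0.1) * pi / 180
  U <- cbind(cos(th1), sin(th1)); V <- cbind(cos(th2), sin(th2))
  for (s in 1:10) {
    bs <- toy_block_set(n = 6, p1 = 2, p2 = 2, seed = 300 + s)
    m <- fit_sgcca(bs, D = 1)
    M <- crossprod(bs$blocks$A, bs$blocks$B) / 5
    grid_max <- 2 * max(U %*% M %*% t(V))
    expect_gt(m$objective, grid_max - 1e-3)
  }
})

test_that("every fit is monotone, unit-norm, sparse and deflation-orthogonal", {
  for (s in 1:10) {
    set.seed(90 + s)
    ids <- paste0("s", 1:15)
    blocks <- list(
      A = matrix(rnorm(15 * 6), 15, 6, dimnames = list(ids, paste0("a", 1:6))),
      B = matrix(rnorm(15 * 5), 15, 5, dimnames = list(ids, paste0("b", 1:5))),
      C = matrix(rnorm(15 * 4), 15, 4, dimnames = list(ids, paste0("c", 1:4))))
    bs <- block_set(blocks)
    m <- fit_sgcca(bs, keepX = list(A = 3, B = 2), D = 2)
    for (d in 1:2) {
      expect_true(all(diff(m$obj_trace[[d]]) >= -1e-9),
                  label = sprintf("monotone ascent seed %d dim %d", s, d))
      for (j in names(blocks)) {
        a <- m$loadings[[j]][, d]
        expect_equal(sum(a^2), 1, tolerance = 1e-8)
      }
      expect_lte(sum(m$loadings$A[, d] != 0), 3)
      expect_lte(sum(m$loadings$B[, d] != 0), 2)
    }
    # deflation orthogonality: s_d' X_{d+1} = 0
    for (j in names(blocks)) {
      X2 <- bs$blocks[[j]] -
        tcrossprod(m$scores[[j]][, 1], m$projections[[j]][1, ])
      expect_lt(max(abs(crossprod(m$scores[[j]][, 1], X2))), 1e-8)
    }
  }
})

test_that("permuting variables within a block permutes loadings identically", {
  bs <- toy_block_set(n = 25, p1 = 6, p2 = 4, seed = 95)
  m <- fit_sgcca(bs, keepX = list(A = 3), D = 1)
  set.seed(96); perm <- sample(6)
  raw <- list(A = bs$blocks$A[, perm], B = bs$blocks$B)
  m2 <- fit_sgcca(block_set(raw, scale = FALSE), keepX = list(A = 3), D = 1)
  expect_equal(unname(m2$loadings$A[, 1]), unname(m$loadings$A[perm, 1]),
               tolerance = 1e-6)
})

test_that("design matrices are validated", {
  bs <- toy_block_set(seed = 97)
  C <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(fit_sgcca(bs, C = C), "symmetric")
  C2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(fit_sgcca(bs, C = C2), "\\[0, 1\\]")
  expect_error(fit_sgcca(bs, keepX = list(A = 9)), "out of range")
  expect_error(fit_sgcca(bs, keepX = list(Z = 2)), "unknown block")
})

test_that("transform reproduces training scores and handles new samples", {
  bs <- toy_block_set(n = 20, seed = 98)
  m <- fit_sgcca(bs, keepX = list(A = 2), D = 2)
  raw <- list(A = sweep(sweep(bs$blocks$A, 2, m$scales$A, "*"), 2,
                        m$centers$A, "+"),
              B = sweep(sweep(bs$blocks$B, 2, m$scales$B, "*"), 2,
                        m$centers$B, "+"))
  sc <- sgcca_transform(m, raw)
  expect_equal(unname(sc$A), unname(m$scores$A), tolerance = 1e-10)
  expect_equal(unname(sc$B), unname(m$scores$B), tolerance = 1e-10)
  # single-sample transform: 1 x D
  one <- lapply(raw, function(b) b[3, , drop = FALSE])
  s1 <- sgcca_transform(m, one)
  expect_equal(dim(s1$A), c(1L, 2L))
  expect_equal(unname(s1$A), unname(m$scores$A[3, , drop = FALSE]),
               tolerance = 1e-10)
  # duplicated rows score identically
  dup <- lapply(raw, function(b) b[c(1:20, 5), ])
  sd2 <- sgcca_transform(m, dup)
  expect_equal(sd2$A[21, ], sd2$A[5, ])
  expect_error(sgcca_transform(m, list(A = raw$A[, -1], B = raw$B)),
               "missing variable")
})

test_that("loading ranks honour keepX and annotate the dominant class", {
  sim <- simulate_glycome(simulation_config(n_control = 60, n_case = 60,
                                            seed = 99))
  pre <- preprocess_glycome(sim$peaks, sim$meta)
  g <- factor(sim$meta$group)
  fit <- fit_diablo(list(peaks = unclass(pre$processed)), g,
                    keepX = list(peaks = 10), D = 1)
  rl <- rank_loadings(fit, "peaks", d = 1, top = 10)
  expect_equal(nrow(rl), 10L)
  expect_true(all(diff(abs(rl$loading)) <= 1e-12))
  expect_true(all(rl$higher_in %in% levels(g)))
  # planted case-up peaks must be annotated as higher in cases
  hits <- rl$variable %in% planted_truth(sim$config)
  expect_true(all(rl$higher_in[hits] == "case"))
  # truncation note when fewer loadings than requested
  rl2 <- rank_loadings(fit, "peaks", d = 1, top = 15)
  expect_equal(nrow(rl2), 10L)
  expect_match(attr(rl2, "note"), "nonzero")
})

test_that("selection agrees with the mixOmics reference implementation", {
  for (s in 1:3) {
    sim <- simulate_glycome(simulation_config(n_control = 100, n_case = 100,
                                              seed = s))
    pre <- preprocess_glycome(sim$peaks, sim$meta)
    g <- factor(sim$meta$group)
    fit <- fit_diablo(list(peaks = unclass(pre$processed)), g,
                      keepX = list(peaks = 10), D = 1)
    mine <- rank_loadings(fit, "peaks", top = 10)$variable
    ref <- mixOmics::selectVar(
      mixOmics::splsda(unclass(pre$processed), g, ncomp = 1, keepX = 10),
      comp = 1)$name
    expect_gte(length(intersect(mine, ref)), 9)
  }
})
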