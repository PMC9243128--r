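sep_fixture <- function(seed = 1, n = 40, effect = 3) {
  set.seed(seed)
  g <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  ids <- paste0("s", seq_len(n))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(ids, paste0("f", 1:6)))
  X[g == "case", 1:3] <- X[g == "case", 1:3] + effect
  list(blocks = list(feat = X), groups = g)
}

test_that("outcome blocks one-hot encode the class factor", {
  g <- factor(c("a", "b", "a", "b"))
  Y <- outcome_block(g, paste0("s", 1:4))
  expect_equal(unname(rowSums(Y)), rep(1, 4))
  expect_equal(colnames(Y), c("a", "b"))
  expect_error(outcome_block(factor(rep("a", 4))), "two classes")
})

test_that("splits are stratified, deterministic and unbiased", {
  g <- factor(rep(c("a", "b"), each = 100))
  sp <- split_train_test(g, fraction = 0.8, seed = 7)
  expect_equal(unname(table(g[sp$train])), array(c(80L, 80L)),
               ignore_attr = TRUE)
  expect_equal(length(sp$test), 40L)
  expect_identical(sp, split_train_test(g, fraction = 0.8, seed = 7))
  expect_error(split_train_test(factor(rep(c("a", "b"), c(3, 50)))),
               "at least 5")
  # long-run test membership frequency ~ 0.2 per sample
  freq <- rowMeans(vapply(1:200, function(s) {
    tabulate(split_train_test(g, 0.8, seed = s)$test, 200)
  }, numeric(200)))
  expect_lt(max(abs(freq - 0.2)), 4 * sqrt(0.2 * 0.8 / 200))
})

test_that("centroid prediction assigns training centroids to their class", {
  fx <- sep_fixture(seed = 10)
  fit <- fit_diablo(fx$blocks, fx$groups, D = 1)
  g <- fx$groups
  tr_scores <- fit$model$scores$feat
  # craft one sample per class whose component score equals the centroid by
  # feeding back the class-mean feature vector
  for (cl in levels(g)) {
    proto <- colMeans(fx$blocks$feat[g == cl, , drop = FALSE])
    nb <- list(feat = matrix(proto, 1, dimnames = list("new", names(proto))))
    pred <- predict(fit, nb)
    expect_equal(as.character(pred$class), cl)
  }
  # single block: ensemble equals the block call
  pred <- predict(fit, fx$blocks)
  expect_equal(as.character(pred$class), unname(pred$block_class[, "feat"]))
  # duplicated test row receives the duplicated call
  dup <- list(feat = fx$blocks$feat[c(1, 1), ])
  pd <- predict(fit, dup)
  expect_equal(pd$class[1], pd$class[2])
  expect_error(predict(fit, fx$blocks, distance = "nope"))
})

test_that("all three prediction distances separate a strong effect", {
  fx <- sep_fixture(seed = 11, effect = 4)
  sp <- split_train_test(fx$groups, 0.8, seed = 11)
  fit <- fit_diablo(list(feat = fx$blocks$feat[sp$train, ]),
                    fx$groups[sp$train], D = 1)
  te <- list(feat = fx$blocks$feat[sp$test, ])
  for (dist in c("centroid-dist", "mahalanobis-dist", "max-dist")) {
    pred <- predict(fit, te, distance = dist)
    expect_equal(mean(pred$class != fx$groups[sp$test]), 0, label = dist)
  }
})

test_that("rank AUC matches hand enumeration and its negation identity", {
  expect_equal(auc(1:4, c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(1:4, c(0, 1, 0, 1)), 0.75)
  expect_equal(auc(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)  # ties = one half
  set.seed(20)
  s <- rnorm(50); l <- rep(0:1, 25)
  expect_equal(auc(s, l), 1 - auc(-s, l), tolerance = 1e-12)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  # null AUC concentrates near one half
  a <- vapply(1:50, function(s) {
    set.seed(s); auc(rnorm(200), rep(0:1, 100))
  }, numeric(1))
  expect_gt(mean(a), 0.47); expect_lt(mean(a), 0.53)
})

test_that("cross-validation is calibrated at null and sharp under signal", {
  sim <- simulate_glycome(simulation_config(n_control = 50, n_case = 50,
                                            effect_size = 2, seed = 30))
  pre <- preprocess_glycome(sim$peaks, sim$meta)
  blocks <- list(peaks = unclass(pre$processed))
  g <- factor(sim$meta$group)
  cv <- cross_validate(blocks, g, folds = 5, seed = 30,
                       keepX = list(peaks = 10), D = 1)
  expect_lt(cv$balanced_error, 0.05)
  # permuted labels: chance-level balanced error
  errs <- vapply(1:8, function(s) {
    set.seed(500 + s)
    cross_validate(blocks, sample(g), folds = 5, seed = s,
                   keepX = list(peaks = 10), D = 1)$balanced_error
  }, numeric(1))
  expect_gt(mean(errs), 0.38); expect_lt(mean(errs), 0.62)
})

test_that("leave-one-out and fold validation follow the contracts", {
  fx <- sep_fixture(seed = 40, n = 10)
  cv <- cross_validate(fx$blocks, fx$groups, folds = 10, seed = 1, D = 1)
  expect_length(cv$fold_errors, 10L)              # one fold per sample
  expect_error(cross_validate(fx$blocks, fx$groups, folds = 7, seed = 1),
               "smallest class")
  expect_error(cross_validate(fx$blocks, fx$groups, folds = 1), ">= 2")
})

test_that("keepX tuning prefers smaller models on ties", {
  fx <- sep_fixture(seed = 50, n = 40, effect = 4)
  cv <- cross_validate(fx$blocks, fx$groups, folds = 4, seed = 2, D = 1,
                       keepX_grid = list(block = "feat", values = c(6, 3)))
  # both grid values separate perfectly; the tie must break to keepX = 3
  expect_equal(unname(cv$grid_errors), c(0, 0))
  expect_equal(cv$chosen_keepX, 3)
})
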