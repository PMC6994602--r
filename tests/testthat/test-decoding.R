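# feature-space fixture with planted class separation on chosen site blocks
sep_features <- function(n_per_class = 30, n_feat = 40, delta = 1, seed = 81) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_feat, delta), n_per_class),
             matrix(rnorm(n_per_class * n_feat, -delta), n_per_class))
  y <- factor(rep(c("face", "nonface"), each = n_per_class),
              levels = c("face", "nonface"))
  list(X = X, y = y)
}

test_that("non-face subsampling balances the subcategories", {
  cats <- rep(c("human_face", NONFACE_CATEGORIES), each = 10)
  idx <- subsample_nonfaces(cats, target = 50, seed = 1)
  sizes <- table(cats[idx])
  expect_equal(sum(sizes), 50)
  expect_setequal(names(sizes), NONFACE_CATEGORIES)
  expect_true(all(sizes %in% 7:8))

  idx7 <- subsample_nonfaces(cats, target = 7, seed = 1)
  expect_true(all(table(cats[idx7]) == 1))

  expect_identical(subsample_nonfaces(cats, target = 50, seed = 9),
                   subsample_nonfaces(cats, target = 50, seed = 9))
  other <- subsample_nonfaces(cats, target = 50, seed = 10)
  expect_false(identical(idx, other))
  expect_identical(sort(as.integer(table(cats[other]))),
                   sort(as.integer(sizes)))

  expect_error(subsample_nonfaces(cats, target = 71), "exceeds")
  expect_error(subsample_nonfaces(rep("human_face", 5)), "at least one epoch")
})

test_that("the linear kernel is the epoch dot-product matrix", {
  X <- diag(4)
  expect_equal(linear_kernel(X), diag(4))

  set.seed(82)
  A <- matrix(rnorm(20), 5)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) brute[i, j] <- sum(A[i, ] * A[j, ])
  expect_equal(linear_kernel(A), brute)

  # block additivity: kernel of concatenated site blocks = sum of per-site kernels
  B <- matrix(rnorm(20), 5)
  expect_equal(linear_kernel(cbind(A, B)),
               linear_kernel(A) + linear_kernel(B))
  expect_error(linear_kernel(A, matrix(0, 2, 3)), "feature dimensions")
})

test_that("balanced accuracy is the mean of the class sensitivities", {
  truth <- rep(c("face", "nonface"), c(10, 10))
  pred <- c(rep("face", 8), "nonface", "nonface",   # sensitivity 0.8
            rep("nonface", 6), rep("face", 4))      # sensitivity 0.6
  expect_equal(balanced_accuracy(truth, pred), 70)
})

test_that("fold partitions are disjoint, exhaustive and stratified", {
  y <- rep(c("face", "nonface"), c(24, 26))
  folds <- ecogface:::make_folds(y, 5, seed = 83)
  expect_setequal(folds, 1:5)
  expect_length(folds, 50)
  per_fold <- table(folds, y)
  expect_true(all(abs(per_fold[, 1] - 24 / 5) < 1))
  expect_true(all(abs(per_fold[, 2] - 26 / 5) < 1))
})

test_that("the cross-validated SVM behaves at chance and at separability", {
  noise <- sep_features(n_per_class = 50, delta = 0, seed = 84)
  r0 <- crossval_svm(linear_kernel(noise$X), noise$y, inner_folds = 0,
                     C_grid = 1, seed = 1)
  expect_lt(abs(r0$balanced_accuracy - 50), 15)

  sep <- sep_features(delta = 1.5, seed = 85)
  r1 <- crossval_svm(linear_kernel(sep$X), sep$y, seed = 1)
  expect_gte(r1$balanced_accuracy, 95)
  # balanced accuracy equals the mean of per-fold values by construction
  expect_equal(r1$balanced_accuracy, mean(r1$fold_accuracy))
  # inner C selection reports one C per fold from the grid
  expect_true(all(r1$fold_C %in% c(0.01, 0.1, 1, 10, 100)))
})

test_that("label permutation yields a chance-centred null and calibrated p", {
  sep <- sep_features(n_per_class = 20, delta = 1.5, seed = 86)
  K <- linear_kernel(sep$X)
  res <- permutation_significance(K, sep$y, n_perm = 200, seed = 2,
                                  outer_folds = 2)
  expect_equal(res$p, 1 / 201)  # strongly separable: minimal attainable p
  expect_lt(abs(mean(res$null_accuracy) - 50), 2)

  noise <- sep_features(n_per_class = 20, delta = 0, seed = 87)
  res0 <- permutation_significance(linear_kernel(noise$X), noise$y,
                                   n_perm = 200, seed = 2, outer_folds = 2)
  expect_gt(res0$p, 0.05)
})

test_that("ablating planted face sites lowers decoding accuracy", {
  effects <- list(
    planted_effect("e01", "human_face", 2.5, latency_ms = 150),
    planted_effect("e02", "human_face", 2.5, latency_ms = 180))
  acc <- vapply(1:6, function(s) {
    bp <- make_bp_fixture(n_sites = 8, images = 10, effects = effects,
                          seed = 200 + s)
    m1 <- run_site_set_model(bp, bp$sites, seed = s, inner_folds = 0,
                             C_grid = 1)
    m2 <- run_site_set_model(bp, setdiff(bp$sites, c("e01", "e02")),
                             seed = s, inner_folds = 0, C_grid = 1)
    c(m1$balanced_accuracy, m2$balanced_accuracy)
  }, numeric(2))
  expect_gt(mean(acc[1, ] - acc[2, ]), 0)
  expect_true(all(acc[1, ] > 60))
})

test_that("a site set equal to all sites reproduces the all-sites model", {
  eff <- planted_effect("e01", "human_face", 3, latency_ms = 150)
  bp <- make_bp_fixture(n_sites = 4, images = 8, effects = list(eff), seed = 88)
  m_all <- run_site_set_model(bp, bp$sites, seed = 3, inner_folds = 0, C_grid = 1)
  m_same <- run_site_set_model(bp, setdiff(bp$sites, character(0)), seed = 3,
                               inner_folds = 0, C_grid = 1)
  expect_equal(m_all$balanced_accuracy, m_same$balanced_accuracy)
  expect_identical(m_all$folds, m_same$folds)
})

test_that("the random-subset ensemble honours its contract", {
  effects <- list(
    planted_effect("e01", "human_face", 3, latency_ms = 150),
    planted_effect("e02", "human_face", 2, latency_ms = 180))
  bp <- make_bp_fixture(n_sites = 9, images = 10, effects = effects, seed = 89)
  face <- c("e01", "e02")
  task <- paste0("e0", 3:9)
  ens <- random_set_models(bp, face, task, size = 4, n_models = 60,
                           seed = 5, outer_folds = 2)
  expect_length(ens$accuracy, 60)
  expect_true(all(vapply(ens$site_sets, function(s) any(s %in% face), TRUE)))
  expect_true(all(lengths(ens$site_sets) == 4))
  expect_true(all(ens$face_proportion > 0))
  # planted signal lives on face sites: accuracy rises with their proportion
  expect_gt(ens$rho, 0)
  expect_error(random_set_models(bp, face, task, size = 20, n_models = 5),
               "exceeds")
})
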