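#' Subsample non-face epochs to balance the classes
#'
#' Draws a balanced subset of non-face epochs whose total matches the target
#' (by default the number of human-face epochs), spreading the draws as
#' equally as possible over the seven non-face subcategories (subset sizes
#' differ by at most one).
#'
#' @param categories Per-epoch category labels.
#' @param target Number of non-face epochs to draw; default the number of
#'   `"human_face"` epochs.
#' @param seed Integer seed.
#' @return Integer vector of selected epoch indices (into `categories`).
#' @export
subsample_nonfaces <- function(categories, target = NULL, seed = 1) {
  idx_by_cat <- lapply(NONFACE_CATEGORIES, function(cc) which(categories == cc))
  names(idx_by_cat) <- NONFACE_CATEGORIES
  if (any(lengths(idx_by_cat) == 0L)) {
    stop("every non-face subcategory must have at least one epoch")
  }
  if (is.null(target)) target <- sum(categories == "human_face")
  if (target > sum(lengths(idx_by_cat))) {
    stop("target exceeds the number of available non-face epochs")
  }
  k <- length(idx_by_cat)
  base <- target %/% k
  rem <- target %% k
  if (any(lengths(idx_by_cat) < base)) {
    stop("a non-face subcategory has too few epochs for an equal split")
  }
  with_seed(seed, {
    eligible <- which(lengths(idx_by_cat) >= base + 1L)
    if (length(eligible) < rem) stop("cannot place the remainder draws")
    plus_one <- if (rem > 0) sample(eligible, rem) else integer(0)
    sizes <- rep(base, k)
    sizes[plus_one] <- base + 1L
    sort(unlist(Map(function(ix, m) {
      if (m == 0L) integer(0) else ix[sample.int(length(ix), m)]
    }, idx_by_cat, sizes), use.names = FALSE))
  })
}

#' Linear kernel (epoch similarity) matrix
#'
#' Entry (i, j) is the dot product between the feature vectors of epochs i
#' and j. For features formed by concatenating per-site blocks, the kernel
#' equals the sum of the per-site kernels (dot-product additivity), the
#' property underpinning the sparse multiple-kernel model.
#'
#' @param a Epochs x features matrix.
#' @param b Optional second matrix (same feature dimension); default `a`.
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
linear_kernel <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature dimensions must match")
  tcrossprod(a, b)
}

#' Balanced accuracy
#'
#' Mean of the per-class sensitivities of a two-class prediction, in percent.
#'
#' @param truth,pred Factors or character vectors of true and predicted
#'   labels.
#' @return Balanced accuracy in \[0, 100\].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  sens <- vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, 0)
  100 * mean(sens)
}

# stratified fold assignment: shuffle within class, deal round-robin
make_folds <- function(labels, k, seed = NULL) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (length(ix) < k) stop("class '", cl, "' has fewer epochs than folds")
      fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

# Soft-margin SVM on a precomputed kernel. SVM(K, C) is exactly equivalent
# to SVM(s*K, C/s) with the dual variables scaled by s; tiny-C problems are
# refit at C = 0.1 on a scaled kernel, where the SMO solver converges much
# faster. The scale is carried on the model so prediction and the MKL
# gradient can undo it.
fit_kernel_svm <- function(K, y, C, tol = 0.001) {
  s <- if (C < 0.1) C / 0.1 else 1
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K * s), y, type = "C-svc",
                     kernel = "matrix", C = C / s, scaled = FALSE, tol = tol)
  attr(m, "kscale") <- s
  m
}

predict_kernel_svm <- function(model, K_test_train) {
  s <- attr(model, "kscale")
  if (is.null(s)) s <- 1
  sv <- kernlab::SVindex(model)
  kernlab::predict(model,
                   kernlab::as.kernelMatrix(s * K_test_train[, sv, drop = FALSE]))
}

# true alpha_i * y_i vector (length n) of a fitted kernel SVM
svm_coefs <- function(model, n) {
  s <- attr(model, "kscale")
  if (is.null(s)) s <- 1
  ya <- rep(0, n)
  ya[kernlab::SVindex(model)] <- unlist(kernlab::coef(model)) * s
  ya
}

#' Cross-validated kernel SVM classification
#'
#' Outer k-fold cross-validation (stratified, non-overlapping) of a
#' soft-margin SVM on a precomputed kernel matrix. Within each outer
#' training set, an inner cross-validation selects the soft-margin parameter
#' C from `C_grid` by inner balanced accuracy (ties broken toward the
#' smallest C, i.e. the strongest regularization); `inner_folds < 2`
#' disables the search and uses `C_grid[1]`.
#'
#' @param K Epochs x epochs kernel matrix.
#' @param labels Two-level factor (or character) of epoch labels.
#' @param outer_folds Number of outer folds, default 5.
#' @param inner_folds Number of inner folds for the C search, default 4.
#' @param C_grid Candidate soft-margin values.
#' @param seed Seed controlling the fold assignment.
#' @param folds Optional explicit outer fold assignment (overrides `seed`),
#'   used to permutation-test a frozen configuration.
#' @param normalize Trace-normalize the kernel to unit mean diagonal before
#'   fitting (default), so the soft-margin grid spans the same effective
#'   regularization range whatever the feature scale.
#' @return A `decoding_result` list: `balanced_accuracy` (%), `fold_accuracy`,
#'   `fold_C`, `sensitivities` (per class, over pooled test predictions),
#'   `folds`, `n`.
#' @export
crossval_svm <- function(K, labels, outer_folds = 5, inner_folds = 4,
                         C_grid = c(0.01, 0.1, 1, 10, 100), seed = 1,
                         folds = NULL, normalize = TRUE) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two levels")
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (normalize && sum(diag(K)) > 0) K <- K * (n / sum(diag(K)))
  if (is.null(folds)) folds <- make_folds(y, outer_folds, seed)
  k <- max(folds)
  fold_acc <- numeric(k)
  fold_C <- numeric(k)
  pred_all <- character(n)
  for (f in seq_len(k)) {
    te <- folds == f
    tr <- !te
    C_best <- C_grid[1]
    if (inner_folds >= 2 && length(C_grid) > 1) {
      yin <- y[tr]
      Kin <- K[tr, tr, drop = FALSE]
      inner <- make_folds(yin, inner_folds, seed = child_seed(seed, 500L + f))
      scores <- vapply(C_grid, function(C) {
        accs <- vapply(seq_len(inner_folds), function(g) {
          ite <- inner == g
          m <- fit_kernel_svm(Kin[!ite, !ite, drop = FALSE], yin[!ite], C)
          p <- predict_kernel_svm(m, Kin[ite, !ite, drop = FALSE])
          balanced_accuracy(yin[ite], p)
        }, 0)
        mean(accs)
      }, 0)
      C_best <- C_grid[which.max(scores)]  # which.max -> first max -> smallest C
    }
    m <- fit_kernel_svm(K[tr, tr, drop = FALSE], y[tr], C_best)
    p <- predict_kernel_svm(m, K[te, tr, drop = FALSE])
    fold_acc[f] <- balanced_accuracy(y[te], p)
    fold_C[f] <- C_best
    pred_all[te] <- as.character(p)
  }
  sens <- vapply(levels(y), function(cl) {
    mean(pred_all[y == cl] == cl)
  }, 0)
  structure(list(balanced_accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 fold_C = fold_C, sensitivities = sens, folds = folds, n = n),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> balanced accuracy %.1f%% over %d folds (n = %d)\n",
              x$balanced_accuracy, length(x$fold_accuracy), x$n))
  if (!is.null(x$p)) cat(sprintf("  permutation p = %.4g\n", x$p))
  invisible(x)
}

#' Permutation significance of a decoder
#'
#' Permutes the epoch labels within the frozen cross-validation structure
#' (identical fold assignment) and recomputes the balanced accuracy;
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams crossval_svm
#' @param n_perm Number of label permutations (default 1000).
#' @param observed Optional precomputed `decoding_result` for these exact
#'   settings; computed if missing.
#' @return The observed `decoding_result` with fields `p` and
#'   `null_accuracy` added.
#' @export
permutation_significance <- function(K, labels, n_perm = 1000, seed = 1,
                                     outer_folds = 5, inner_folds = 0,
                                     C_grid = 1, observed = NULL) {
  y <- factor(labels)
  folds <- make_folds(y, outer_folds, seed)
  if (is.null(observed)) {
    observed <- crossval_svm(K, y, inner_folds = inner_folds, C_grid = C_grid,
                             seed = seed, folds = folds)
  }
  null <- with_seed(child_seed(seed, 999L), {
    vapply(seq_len(n_perm), function(i) {
      yp <- y[sample.int(length(y))]
      crossval_svm(K, yp, inner_folds = inner_folds, C_grid = C_grid,
                   seed = seed, folds = folds)$balanced_accuracy
    }, 0)
  })
  observed$p <- (1 + sum(null >= observed$balanced_accuracy)) / (n_perm + 1)
  observed$null_accuracy <- null
  observed
}

#' Build a balanced face / non-face feature set
#'
#' Collects the human-face epochs and a balanced subsample of non-face
#' epochs (via [subsample_nonfaces()]) and flattens, per epoch, the smoothed
#' band power of the requested sites over the analysis window into one
#' feature vector (features = sites x time points).
#'
#' @param bp A [bp_epochs()].
#' @param sites Character vector of site labels to include.
#' @param window Analysis window in ms (closed), default `c(150, 500)`.
#' @param seed Seed for the non-face subsampling.
#' @return List with `X` (epochs x features), `y` (factor face/nonface),
#'   `epochs` (row indices into `bp`), `sites`, `n_time`.
#' @export
build_feature_set <- function(bp, sites, window = c(150, 500), seed = 1) {
  stopifnot(inherits(bp, "bp_epochs"))
  si <- match(sites, bp$sites)
  if (anyNA(si)) stop("unknown sites: ", paste(sites[is.na(si)], collapse = ", "))
  if (!length(si)) stop("site set is empty")
  wi <- window_idx(bp$times, window)
  face_idx <- which(bp$categories == "human_face")
  nf_idx <- subsample_nonfaces(bp$categories, seed = seed)
  rows <- c(face_idx, nf_idx)
  X <- matrix(0, length(rows), length(si) * length(wi))
  for (j in seq_along(si)) {
    X[, (j - 1L) * length(wi) + seq_along(wi)] <-
      matrix(bp$power[rows, si[j], wi], length(rows), length(wi))
  }
  y <- factor(rep(c("face", "nonface"), c(length(face_idx), length(nf_idx))),
              levels = c("face", "nonface"))
  list(X = X, y = y, epochs = rows, sites = sites, n_time = length(wi))
}

#' Decode faces from a configurable site set
#'
#' The full decoding pipeline for one site set (instantiating the all-sites,
#' excluding-face-sites and excluding-task-active-sites model variants):
#' balanced feature set, linear kernel, cross-validated soft-margin SVM, and
#' optionally a label-permutation significance test.
#'
#' @inheritParams build_feature_set
#' @inheritParams crossval_svm
#' @param n_perm If > 0, also run [permutation_significance()] with this
#'   many permutations.
#' @param model Optional label stored on the result (e.g. `"I"`, `"II"`).
#' @return A `decoding_result` with extra fields `sites` and `model`.
#' @export
run_site_set_model <- function(bp, sites, window = c(150, 500), seed = 1,
                               outer_folds = 5, inner_folds = 4,
                               C_grid = c(0.01, 0.1, 1, 10, 100),
                               n_perm = 0, model = NULL) {
  fs <- build_feature_set(bp, sites, window, seed)
  K <- linear_kernel(fs$X)
  res <- if (n_perm > 0) {
    permutation_significance(K, fs$y, n_perm = n_perm, seed = seed,
                             outer_folds = outer_folds,
                             inner_folds = inner_folds, C_grid = C_grid)
  } else {
    crossval_svm(K, fs$y, outer_folds = outer_folds,
                 inner_folds = inner_folds, C_grid = C_grid, seed = seed)
  }
  res$sites <- sites
  res$model <- model
  res
}

#' Random-subset site ensemble
#'
#' Builds `n_models` decoding models over random site subsets of fixed
#' `size`, drawn without replacement from the union of face-selective and
#' task-active sites with the constraint that each subset contains at least
#' one face-selective site. All models share the same epochs, folds and
#' hyperparameters; only the site sets differ. The proportion of
#' face-selective sites per model is recorded and its Spearman correlation
#' with balanced accuracy is returned.
#'
#' @param bp A [bp_epochs()].
#' @param face_sites,task_sites Character vectors of face-selective and
#'   task-active site labels.
#' @param size Number of sites per model (e.g. the size of the
#'   excluding-face-sites model's set).
#' @param n_models Number of random subsets, default 499.
#' @param window Analysis window (ms).
#' @param seed Master seed.
#' @param outer_folds,inner_folds,C_grid Cross-validation settings (the
#'   default disables the inner C search for ensemble-scale runs).
#' @return List with `accuracy` (per model, %), `face_proportion`,
#'   `site_sets`, `rho` and `rho_p` (Spearman accuracy vs proportion), and
#'   `n_models`.
#' @export
random_set_models <- function(bp, face_sites, task_sites, size,
                              n_models = 499, window = c(150, 500), seed = 1,
                              outer_folds = 5, inner_folds = 0, C_grid = 1) {
  pool <- c(face_sites, task_sites)
  if (size > length(pool)) stop("size exceeds the available site pool")
  if (!length(face_sites)) stop("at least one face-selective site is required")
  fs <- build_feature_set(bp, pool, window, seed)
  n_time <- fs$n_time
  # per-site kernels; a subset's kernel is the sum of its members' kernels
  Ks <- lapply(seq_along(pool), function(j) {
    cols <- (j - 1L) * n_time + seq_len(n_time)
    linear_kernel(fs$X[, cols, drop = FALSE])
  })
  names(Ks) <- pool
  folds <- make_folds(fs$y, outer_folds, seed)
  sets <- with_seed(child_seed(seed, 7L), {
    lapply(seq_len(n_models), function(i) {
      repeat {
        s <- sample(pool, size)
        if (any(s %in% face_sites)) return(s)
      }
    })
  })
  acc <- vapply(sets, function(s) {
    K <- Reduce(`+`, Ks[s])
    crossval_svm(K, fs$y, inner_folds = inner_folds, C_grid = C_grid,
                 seed = seed, folds = folds)$balanced_accuracy
  }, 0)
  prop <- vapply(sets, function(s) mean(s %in% face_sites), 0)
  ct <- suppressWarnings(cor.test(acc, prop, method = "spearman",
                                  exact = FALSE))
  list(accuracy = acc, face_proportion = prop, site_sets = sets,
       rho = unname(ct$estimate), rho_p = ct$p.value, n_models = n_models)
}
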