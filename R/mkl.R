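#' Sparse multiple kernel learning over sites or bands
#'
#' Learns a sparsity-inducing convex combination of kernels (one linear
#' kernel per site, per frequency band, or per feature set) wrapped around
#' the same soft-margin SVM used by [crossval_svm()]. The kernel weights are
#' optimized by alternating between fitting the SVM on the combined kernel
#' and taking a reduced-gradient step on the weights with Euclidean
#' projection onto the probability simplex; the simplex projection is what
#' drives weights of uninformative kernels to exactly zero. Convergence is
#' declared when the largest weight change drops below `tol`, within an
#' iteration cap; non-converged folds are flagged but still contribute
#' their current weights.
#'
#' Kernels are trace-normalized before combination (so kernels with larger
#' variance do not dominate); disable with `normalize = FALSE`.
#'
#' @param kernels Named list of epochs x epochs kernel matrices (>= 1).
#' @param labels Two-level factor of epoch labels.
#' @param C_grid Candidate soft-margin values; within each outer fold an
#'   inner cross-validation selects C by inner balanced accuracy of the
#'   full sparse model (ties toward the smallest C), mirroring the plain
#'   kernel SVM protocol. A single value fixes C.
#' @param outer_folds,inner_folds Stratified cross-validation structure;
#'   `inner_folds < 2` disables the C search.
#' @param seed Seed controlling the fold assignment.
#' @param max_iter Iteration cap for the weight optimization, default 200.
#' @param tol Convergence tolerance on the weight change, default 1e-4.
#' @param max_iter_inner Coarser iteration cap used for the fits inside the
#'   inner C search (the final per-fold fit always gets the full budget).
#' @param normalize Trace-normalize kernels before combination.
#' @param zero_tol Weights below this value count as null contributions.
#' @return A `decoding_result` with extra fields `contributions` (named,
#'   non-negative, summing to 1: the fold-averaged kernel weights),
#'   `fold_weights` (matrix folds x kernels), `sparsity` (fold-averaged
#'   fraction of non-null contributions) and `converged`.
#' @export
sparse_mkl <- function(kernels, labels, C_grid = c(0.01, 0.1, 1, 10, 100),
                       outer_folds = 5, inner_folds = 4, seed = 1,
                       max_iter = 200, tol = 1e-4, max_iter_inner = 25,
                       normalize = TRUE, zero_tol = 1e-3) {
  if (!length(kernels)) stop("at least one kernel is required")
  if (is.null(names(kernels))) names(kernels) <- paste0("k", seq_along(kernels))
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two levels")
  n <- length(y)
  M <- length(kernels)
  if (normalize) {
    kernels <- lapply(kernels, function(K) K * n / sum(diag(K)))
  }
  folds <- make_folds(y, outer_folds, seed)
  k <- max(folds)
  fold_acc <- numeric(k)
  fold_C <- numeric(k)
  fold_w <- matrix(0, k, M, dimnames = list(NULL, names(kernels)))
  fold_sparsity <- numeric(k)
  converged <- logical(k)
  pred_all <- character(n)
  for (f in seq_len(k)) {
    te <- folds == f
    tr <- !te
    Ktr <- lapply(kernels, function(K) K[tr, tr, drop = FALSE])
    C_best <- C_grid[1]
    if (inner_folds >= 2 && length(C_grid) > 1) {
      yin <- y[tr]
      inner <- make_folds(yin, inner_folds, seed = child_seed(seed, 500L + f))
      scores <- vapply(C_grid, function(C) {
        mean(vapply(seq_len(inner_folds), function(g) {
          ite <- inner == g
          Kii <- lapply(Ktr, function(K) K[!ite, !ite, drop = FALSE])
          opt_i <- mkl_optimize(Kii, yin[!ite], C, max_iter_inner, tol,
                                rel_tol = 1e-4, max_eval = 60)
          Kti <- Reduce(`+`, Map(function(K, w) w * K[ite, !ite, drop = FALSE],
                                 Ktr, opt_i$d))
          balanced_accuracy(yin[ite], predict_kernel_svm(opt_i$model, Kti))
        }, 0))
      }, 0)
      C_best <- C_grid[which.max(scores)]  # first max -> smallest C
    }
    opt <- mkl_optimize(Ktr, y[tr], C_best, max_iter, tol)
    fold_C[f] <- C_best
    fold_w[f, ] <- opt$d
    converged[f] <- opt$converged
    fold_sparsity[f] <- mean(opt$d > zero_tol)
    Kte <- Reduce(`+`, Map(function(K, w) w * K[te, tr, drop = FALSE],
                           kernels, opt$d))
    p <- predict_kernel_svm(opt$model, Kte)
    fold_acc[f] <- balanced_accuracy(y[te], p)
    pred_all[te] <- as.character(p)
  }
  contributions <- colMeans(fold_w)
  if (sum(contributions) > 0) contributions <- contributions / sum(contributions)
  sens <- vapply(levels(y), function(cl) mean(pred_all[y == cl] == cl), 0)
  structure(list(balanced_accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 fold_C = fold_C, sensitivities = sens, folds = folds,
                 n = n, contributions = contributions, fold_weights = fold_w,
                 sparsity = mean(fold_sparsity), converged = all(converged)),
            class = "decoding_result")
}

# Alternating optimization of the kernel weights on the training set:
# projected gradient with a step size carried across iterations and a hard
# budget on SVM evaluations.
mkl_optimize <- function(Ks, y, C, max_iter, tol, rel_tol = 1e-6,
                         max_eval = 400) {
  M <- length(Ks)
  d <- rep(1 / M, M)
  if (M == 1L) {
    m <- fit_kernel_svm(Ks[[1]], y, C)
    return(list(d = 1, model = m, converged = TRUE))
  }
  evaluate <- function(d) {
    K <- Reduce(`+`, Map(`*`, Ks, d))
    # coarse KKT tolerance: the weight loop has its own convergence control
    m <- fit_kernel_svm(K, y, C, tol = 0.05)
    ya <- svm_coefs(m, length(y))
    J <- sum(abs(ya)) - 0.5 * drop(crossprod(ya, K %*% ya))
    grad <- vapply(Ks, function(Km) {
      -0.5 * drop(crossprod(ya, Km %*% ya))
    }, 0)
    list(J = J, grad = grad, model = m)
  }
  st <- evaluate(d)
  n_eval <- 1L
  converged <- FALSE
  eta <- NULL
  for (it in seq_len(max_iter)) {
    g <- st$grad
    if (is.null(eta)) eta <- 1 / max(abs(g), 1e-12)
    improved <- FALSE
    for (bt in 1:12) {
      if (n_eval >= max_eval) break
      d_new <- project_simplex(d - eta * g)
      st_new <- evaluate(d_new)
      n_eval <- n_eval + 1L
      if (st_new$J < st$J - 1e-12 * max(1, abs(st$J))) { improved <- TRUE; break }
      eta <- eta / 2
    }
    if (!improved) { converged <- n_eval < max_eval; break }
    delta <- max(abs(d_new - d))
    dJ <- abs(st$J - st_new$J)
    d <- d_new
    st <- st_new
    eta <- eta * 2  # allow the step to grow again after a success
    if (delta < tol || dJ < rel_tol * max(1, abs(st$J))) { converged <- TRUE; break }
  }
  list(d = d, model = st$model, converged = converged)
}

# Euclidean projection of a vector onto the probability simplex
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Per-site kernels from band-power epochs
#'
#' Builds one linear kernel per site over the analysis window, on the same
#' balanced face / non-face epoch set used by [run_site_set_model()].
#'
#' @inheritParams build_feature_set
#' @return List with `kernels` (named per-site list), `y`, `epochs`.
#' @export
site_kernels <- function(bp, sites, window = c(150, 500), seed = 1) {
  fs <- build_feature_set(bp, sites, window, seed)
  n_time <- fs$n_time
  kernels <- lapply(seq_along(sites), function(j) {
    cols <- (j - 1L) * n_time + seq_len(n_time)
    linear_kernel(fs$X[, cols, drop = FALSE])
  })
  names(kernels) <- sites
  list(kernels = kernels, y = fs$y, epochs = fs$epochs)
}

#' Sparsity of a contribution map
#'
#' The fraction of kernels (sites or bands) with a non-null contribution.
#'
#' @param contributions Non-negative contribution vector.
#' @param zero_tol Contributions at or below this value count as null.
#' @return Fraction in \[0, 1\].
#' @export
kernel_sparsity <- function(contributions, zero_tol = 0) {
  mean(contributions > zero_tol)
}

#' Correlate model contributions with site selectivity
#'
#' Pearson correlation between the contribution of each site to the sparse
#' model and its human-face selectivity score, optionally also within
#' subjects.
#'
#' @param contributions Named or positional contribution vector.
#' @param selectivity Selectivity scores aligned with `contributions`.
#' @param subject Optional per-site subject identifier.
#' @return List with `r`, `p`, `n`, and (when `subject` is given)
#'   `per_subject` data frame.
#' @export
contribution_selectivity_correlation <- function(contributions, selectivity,
                                                 subject = NULL) {
  if (length(contributions) != length(selectivity)) {
    stop("contributions and selectivity must be aligned")
  }
  ct <- cor.test(contributions, selectivity, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value,
              n = length(contributions))
  if (!is.null(subject)) {
    per <- lapply(split(seq_along(subject), subject), function(ix) {
      if (length(ix) < 3 || sd(contributions[ix]) == 0 ||
          sd(selectivity[ix]) == 0) return(NULL)
      cc <- cor.test(contributions[ix], selectivity[ix])
      data.frame(subject = subject[ix[1]], r = unname(cc$estimate),
                 p = cc$p.value, n = length(ix))
    })
    out$per_subject <- do.call(rbind, per)
  }
  out
}
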