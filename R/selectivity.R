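#' Classify recording sites by category responses
#'
#' Univariate, permutation-based classification of every site:
#' \describe{
#'   \item{active}{at least one category's mean response in the analysis
#'     window differs from its own baseline (paired sign-flip test per
#'     category, BH-FDR over the full site x category family at level `q`).}
#'   \item{face_selective}{among active sites, pooled responses to the four
#'     face categories exceed pooled non-face responses (one-sided unpaired
#'     test, BH-FDR over the active sites).}
#'   \item{human_face_selective}{among active sites, human-face responses
#'     exceed pooled non-face responses (one-sided, BH-FDR over active
#'     sites).}
#'   \item{task_active}{active but neither face- nor human-face-selective.}
#' }
#' The selectivity score of a site is the difference in mean windowed dB
#' between human faces and pooled non-faces. Response-block trials are
#' always excluded.
#'
#' @param bp A [bp_epochs()] with all eleven stimulus categories present.
#' @param window Analysis window in ms (closed), default `c(150, 500)`.
#' @param baseline Baseline window in ms (half-open), default `c(-100, 0)`.
#' @param q FDR level, default 0.05.
#' @param n_perm_active Permutations for the activity (paired) tests.
#' @param n_perm_select Permutations for the selectivity (unpaired) tests.
#' @param seed Master seed; per-test streams are derived by counter so that
#'   results do not depend on site order.
#' @return A `site_classification` data frame: per site `site`, `y` (MNI, if
#'   a layout is attached), `p_active`, `p_face`, `p_human_face`, flags
#'   `active`, `face_selective`, `human_face_selective`, `task_active`, and
#'   `selectivity` (dB). Per-category mean responses are attached as the
#'   `category_means` attribute.
#' @export
classify_sites <- function(bp, window = c(150, 500), baseline = c(-100, 0),
                           q = 0.05, n_perm_active = 50000,
                           n_perm_select = 10000, seed = 1) {
  stopifnot(inherits(bp, "bp_epochs"))
  stim <- bp$categories != RESPONSE_BLOCK
  cats <- bp$categories[stim]
  missing <- setdiff(STIM_CATEGORIES, unique(cats))
  if (length(missing)) {
    stop("missing categories: ", paste(missing, collapse = ", "))
  }
  n_site <- length(bp$sites)
  wi <- window_idx(bp$times, window)
  bi <- window_idx_halfopen(bp$times, baseline)
  W <- apply(bp$power[stim, , wi, drop = FALSE], c(1, 2), mean)
  B <- apply(bp$power[stim, , bi, drop = FALSE], c(1, 2), mean)

  # activity: paired test per site x category, FDR over the whole family
  p_act <- matrix(NA_real_, n_site, length(STIM_CATEGORIES),
                  dimnames = list(bp$sites, STIM_CATEGORIES))
  cat_means <- p_act
  for (s in seq_len(n_site)) {
    for (ci in seq_along(STIM_CATEGORIES)) {
      tr <- cats == STIM_CATEGORIES[ci]
      cat_means[s, ci] <- mean(W[tr, s])
      p_act[s, ci] <- permutation_test_paired(
        W[tr, s], B[tr, s], n_perm = n_perm_active,
        seed = child_seed(seed, s * 100L + ci))$p
    }
  }
  act_mask <- matrix(fdr_bh(as.vector(p_act), q), n_site)
  active <- rowSums(act_mask) > 0
  p_active <- apply(p_act, 1, min)

  face_tr <- cats %in% FACE_CATEGORIES
  nonface_tr <- cats %in% NONFACE_CATEGORIES
  human_tr <- cats == "human_face"

  p_face <- p_human <- rep(NA_real_, n_site)
  for (s in which(active)) {
    p_face[s] <- permutation_test_unpaired(
      W[face_tr, s], W[nonface_tr, s], n_perm = n_perm_select,
      alternative = "greater", seed = child_seed(seed, 20000L + s))$p
    p_human[s] <- permutation_test_unpaired(
      W[human_tr, s], W[nonface_tr, s], n_perm = n_perm_select,
      alternative = "greater", seed = child_seed(seed, 40000L + s))$p
  }
  face_sel <- human_sel <- rep(FALSE, n_site)
  if (any(active)) {
    face_sel[active] <- fdr_bh(p_face[active], q)
    human_sel[active] <- fdr_bh(p_human[active], q)
  }
  selectivity <- colMeans(W[human_tr, , drop = FALSE]) -
    colMeans(W[nonface_tr, , drop = FALSE])

  out <- data.frame(
    site = bp$sites,
    y = if (!is.null(bp$layout)) bp$layout$y[match(bp$sites, bp$layout$name)]
        else NA_real_,
    p_active = p_active, p_face = p_face, p_human_face = p_human,
    active = active, face_selective = face_sel,
    human_face_selective = human_sel,
    task_active = active & !face_sel & !human_sel,
    selectivity = selectivity,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("site_classification", "data.frame"),
            category_means = cat_means, window = window, q = q)
}

#' Pairwise comparison of face subcategories
#'
#' Compares the windowed mean responses to the four face subcategories
#' (human, mammal, bird, marine), pooling trials over each supplied site
#' set: all six pairs are tested with two-sided unpaired permutation tests
#' and BH-FDR corrected jointly over every pair x set combination (12 tests
#' when both the face-selective and task-active sets are given).
#'
#' @param bp A [bp_epochs()].
#' @param site_sets Named list of character vectors of site labels (or one
#'   character vector).
#' @param window Analysis window in ms, default `c(150, 500)`.
#' @param n_perm Permutations per test.
#' @param q FDR level.
#' @param seed Master seed.
#' @return Data frame with one row per pair and set: `set`, `cat_a`,
#'   `cat_b`, `mean_a`, `mean_b`, `statistic`, `p`, `significant`.
#' @export
compare_face_subcategories <- function(bp, site_sets, window = c(150, 500),
                                       n_perm = 10000, q = 0.05, seed = 1) {
  stopifnot(inherits(bp, "bp_epochs"))
  if (!is.list(site_sets)) site_sets <- list(sites = site_sets)
  if (is.null(names(site_sets))) names(site_sets) <- paste0("set", seq_along(site_sets))
  wi <- window_idx(bp$times, window)
  pairs <- utils::combn(FACE_CATEGORIES, 2)
  rows <- list()
  ctr <- 0L
  for (set_name in names(site_sets)) {
    sites <- site_sets[[set_name]]
    if (!length(sites)) stop("site set '", set_name, "' is empty")
    si <- match(sites, bp$sites)
    if (anyNA(si)) stop("unknown sites in set '", set_name, "'")
    v <- apply(bp$power[, si, wi, drop = FALSE], 1, mean)
    for (j in seq_len(ncol(pairs))) {
      ctr <- ctr + 1L
      a <- v[bp$categories == pairs[1, j]]
      b <- v[bp$categories == pairs[2, j]]
      tst <- permutation_test_unpaired(a, b, n_perm = n_perm,
                                       seed = child_seed(seed, ctr))
      rows[[ctr]] <- data.frame(
        set = set_name, cat_a = pairs[1, j], cat_b = pairs[2, j],
        mean_a = mean(a), mean_b = mean(b),
        statistic = tst$statistic, p = tst$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p, q)
  out
}

#' Per-band site classification
#'
#' Runs the band-power extraction and [classify_sites()] independently for
#' each named frequency band.
#'
#' @param epochs An [ecog_epochs()].
#' @param bands Named list of band limits, default [band_specs()].
#' @param freq_step Wavelet frequency step in Hz.
#' @param ... Passed on to [classify_sites()].
#' @return Named list of `site_classification` results, one per band.
#' @export
band_scan <- function(epochs, bands = band_specs(), freq_step = 1, ...) {
  stopifnot(inherits(epochs, "ecog_epochs"))
  out <- lapply(names(bands), function(nm) {
    bp <- band_power(epochs, band = bands[[nm]], freq_step = freq_step,
                     band_name = nm)
    classify_sites(bp, ...)
  })
  names(out) <- names(bands)
  out
}
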