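# fixture with one face site, one human-face-only site, one all-category
# site and noise sites, 20 trials per category
selectivity_fixture <- function(seed = 71) {
  effects <- list(
    planted_effect("e01", FACE_CATEGORIES, amplitude_db = 3, latency_ms = 150),
    planted_effect("e02", "human_face", amplitude_db = 3, latency_ms = 150),
    planted_effect("e03", STIM_CATEGORIES, amplitude_db = 3, latency_ms = 150))
  make_bp_fixture(n_sites = 6, images = 10, effects = effects, seed = seed)
}

test_that("planted response profiles map onto the site classes", {
  bp <- selectivity_fixture()
  cls <- classify_sites(bp, n_perm_active = 1500, n_perm_select = 1500, seed = 1)

  # responds to pooled faces: face-selective (and necessarily active)
  expect_true(cls$active[1])
  expect_true(cls$face_selective[1])
  # responds only to human faces: human-face-selective; the pooled-face
  # contrast is diluted by the three silent face subcategories
  expect_true(cls$active[2])
  expect_true(cls$human_face_selective[2])
  # equal response to every category: active but in no selective class
  expect_true(cls$active[3])
  expect_false(cls$face_selective[3])
  expect_false(cls$human_face_selective[3])
  expect_true(cls$task_active[3])
  # class algebra
  expect_true(all(cls$site[cls$human_face_selective] %in% cls$site[cls$active]))
  expect_false(any(cls$task_active & (cls$face_selective | cls$human_face_selective)))
  # selectivity score is the human-face minus pooled-non-face windowed mean
  expect_gt(cls$selectivity[2], 2)
  expect_lt(abs(cls$selectivity[3]), 0.5)
})

test_that("classification is invariant to site and trial ordering", {
  bp <- selectivity_fixture()
  cls <- classify_sites(bp, n_perm_active = 800, n_perm_select = 800, seed = 2)

  perm_sites <- c(4, 2, 6, 1, 3, 5)
  bp2 <- bp
  bp2$power <- bp$power[, perm_sites, , drop = FALSE]
  bp2$power_raw <- bp$power_raw[, perm_sites, , drop = FALSE]
  bp2$sites <- bp$sites[perm_sites]
  bp2$layout <- bp$layout[perm_sites, ]
  cls2 <- classify_sites(bp2, n_perm_active = 800, n_perm_select = 800, seed = 2)
  ord <- match(cls$site, cls2$site)
  expect_identical(cls$active, cls2$active[ord])
  expect_identical(cls$human_face_selective, cls2$human_face_selective[ord])
  expect_equal(cls$selectivity, cls2$selectivity[ord])

  set.seed(3)
  perm_tr <- sample(dim(bp$power)[1])
  bp3 <- bp
  bp3$power <- bp$power[perm_tr, , , drop = FALSE]
  bp3$power_raw <- bp$power_raw[perm_tr, , , drop = FALSE]
  bp3$categories <- bp$categories[perm_tr]
  cls3 <- classify_sites(bp3, n_perm_active = 800, n_perm_select = 800, seed = 2)
  expect_identical(cls$active, cls3$active)
  expect_equal(cls$selectivity, cls3$selectivity)
})

test_that("a missing category is an error", {
  bp <- selectivity_fixture()
  keep <- bp$categories != "places"
  bp$power <- bp$power[keep, , , drop = FALSE]
  bp$power_raw <- bp$power_raw[keep, , , drop = FALSE]
  bp$categories <- bp$categories[keep]
  expect_error(classify_sites(bp, n_perm_active = 500), "missing categories")
})

test_that("face subcategory comparisons recover a planted amplitude ordering", {
  # human > mammal > bird = marine, mirroring the reported response ordering
  effects <- list(
    planted_effect("e01", "human_face", 5.2, latency_ms = 150),
    planted_effect("e01", "mammal_face", 4.0, latency_ms = 150),
    planted_effect("e01", "bird_face", 3.0, latency_ms = 150),
    planted_effect("e01", "marine_face", 3.0, latency_ms = 150))
  bp <- make_bp_fixture(n_sites = 2, images = 13, effects = effects,
                        seed = 72, noise_sd_db = 0.8)
  res <- compare_face_subcategories(bp, list(face = "e01"),
                                    n_perm = 2000, seed = 4)
  expect_equal(nrow(res), 6)
  bm <- res$cat_a == "bird_face" & res$cat_b == "marine_face"
  expect_false(res$significant[bm])
  expect_true(all(res$significant[!bm]))
})

test_that("subcategory tests are symmetric and silent on equal amplitudes", {
  effects <- list(planted_effect("e01", FACE_CATEGORIES, 3, latency_ms = 150))
  bp <- make_bp_fixture(n_sites = 2, images = 8, effects = effects, seed = 73)
  res <- compare_face_subcategories(bp, list(face = "e01"),
                                    n_perm = 1200, seed = 5)
  expect_false(any(res$significant))
  # two-sided p unchanged when the pair order is swapped
  wi <- bp$times >= 150 & bp$times <= 500
  v <- apply(bp$power[, 1, wi], 1, mean)
  a <- v[bp$categories == "human_face"]
  b <- v[bp$categories == "mammal_face"]
  p_ab <- permutation_test_unpaired(a, b, n_perm = 1500, seed = 6)$p
  p_ba <- permutation_test_unpaired(b, a, n_perm = 1500, seed = 6)$p
  expect_equal(p_ab, p_ba, tolerance = 0.05)
})

test_that("a 12-test family is corrected jointly for two site sets", {
  bp <- selectivity_fixture()
  res <- compare_face_subcategories(bp, list(face = "e01", task = "e03"),
                                    n_perm = 500, seed = 7)
  expect_equal(nrow(res), 12)
  expect_setequal(unique(res$set), c("face", "task"))
})

test_that("an effect confined to high gamma is flagged in HFB and not in theta", {
  design <- make_task_design(10, 2, seed = 74)
  layout <- make_electrode_layout(4, seed = 74)
  eff <- planted_effect("e02", "human_face", amplitude_db = 4, latency_ms = 150)
  raw <- simulate_raw(design, layout, list(eff), seed = 74)
  raw <- notch_filter(raw)
  ep <- reject_artifact_epochs(epoch_and_baseline(raw, design))
  scan <- band_scan(ep, bands = band_specs()[c("theta", "HFB")],
                    freq_step = 1, n_perm_active = 1200,
                    n_perm_select = 1200, seed = 8)
  expect_true(scan$HFB$human_face_selective[2])
  expect_false(scan$theta$active[2])
  # per-band scan agrees with running the stages by hand
  direct <- classify_sites(band_power(ep, band = c(70, 177), freq_step = 1),
                           n_perm_active = 1200, n_perm_select = 1200, seed = 8)
  expect_identical(scan$HFB$active, direct$active)
  expect_identical(scan$HFB$human_face_selective, direct$human_face_selective)
})
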