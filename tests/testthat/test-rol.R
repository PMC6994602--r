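# enumeration oracle: first run of >= n_consec bins (half-open [t, t+30),
# step 2 ms) whose means all exceed the threshold
oracle_onset <- function(trace, times, threshold, width = 30, step = 2,
                         n_consec = 25, search0 = 0) {
  starts <- seq(search0, max(times) - width + 1, by = step)
  above <- vapply(starts, function(s) {
    mean(trace[times >= s & times < s + width]) > threshold
  }, TRUE)
  for (i in seq_len(length(starts) - n_consec + 1)) {
    if (all(above[i:(i + n_consec - 1)])) return(starts[i])
  }
  NA_real_
}

test_that("a flat zero trace is undetected under the strict threshold", {
  expect_true(is.na(rol_trial(rep(0, 900), EPOCH_TIMES)))
})

test_that("a noiseless step is detected at the bin-convention onset", {
  tr <- as.numeric(EPOCH_TIMES >= 200)
  expect_equal(rol_trial(tr, EPOCH_TIMES, threshold = 0),
               oracle_onset(tr, EPOCH_TIMES, 0))
  expect_equal(rol_trial(tr, EPOCH_TIMES, threshold = 0), 172)
  # half-open bins: a step at exactly 200 ms is missed by the [170, 200) bin
  expect_true(mean(tr[EPOCH_TIMES >= 170 & EPOCH_TIMES < 200]) == 0)
})

test_that("bin means agree with the enumeration oracle on noisy traces", {
  set.seed(101)
  for (i in 1:5) {
    tr <- cumsum(rnorm(900)) / 20
    expect_equal(rol_trial(tr, EPOCH_TIMES, threshold = 0.3),
                 oracle_onset(tr, EPOCH_TIMES, 0.3))
  }
})

test_that("planted ramp onsets 100 ms apart are recovered within 10 ms", {
  set.seed(102)
  A <- smooth_noise_trials(60)
  amp <- 0.5
  tr1 <- A[1:30, ] * 0.3 +
    matrix(rep(amp * ramp_shape(EPOCH_TIMES, 150), 30), 30, byrow = TRUE)
  tr2 <- A[31:60, ] * 0.3 +
    matrix(rep(amp * ramp_shape(EPOCH_TIMES, 250), 30), 30, byrow = TRUE)
  r1 <- rol_site(tr1, EPOCH_TIMES)
  r2 <- rol_site(tr2, EPOCH_TIMES)
  expect_true(r1$valid && r2$valid)
  expect_lt(abs((r2$median_ms - r1$median_ms) - 100), 10)
})

test_that("onset detection is invariant to trial amplitude scaling", {
  set.seed(103)
  tr <- smooth_noise_trials(20) * 0.3 +
    matrix(rep(0.5 * ramp_shape(EPOCH_TIMES, 180), 20), 20, byrow = TRUE)
  r <- rol_site(tr, EPOCH_TIMES)
  r7 <- rol_site(tr * 7, EPOCH_TIMES)
  expect_identical(r$onsets, r7$onsets)
  # noiseless sweep: normalized ramps give identical onsets at every SNR
  B <- smooth_noise_trials(10)
  base <- matrix(0.2, 5, 900)
  onsets <- lapply(c(2, 5, 10), function(s) {
    inj <- inject_ramp(base, B, EPOCH_TIMES, s)
    rol_site(matrix(inj, nrow = 5), EPOCH_TIMES)$onsets
  })
  expect_identical(onsets[[1]], onsets[[2]])
  expect_identical(onsets[[2]], onsets[[3]])
})

test_that("delaying a trace delays the detected onset equally", {
  set.seed(104)
  delay <- 24  # a multiple of the 2 ms bin step
  # exact at fixed threshold: the bin grid translates with the trace
  for (i in 1:5) {
    tr <- as.numeric(stats::filter(rnorm(900), rep(0.05, 20), sides = 2,
                                   circular = TRUE)) * 0.3 +
      0.5 * ramp_shape(EPOCH_TIMES, 150)
    shifted <- c(rep(0, delay), tr[1:(900 - delay)])
    o1 <- rol_trial(tr, EPOCH_TIMES, threshold = 0.3)
    o2 <- rol_trial(shifted, EPOCH_TIMES, threshold = 0.3)
    expect_equal(o2 - o1, delay)
  }
  # at the site level the threshold is re-estimated from the shifted
  # baseline, so equivariance holds to bin-step resolution
  trs <- smooth_noise_trials(15) * 0.3 +
    matrix(rep(0.5 * ramp_shape(EPOCH_TIMES, 150), 15), 15, byrow = TRUE)
  shifted <- cbind(matrix(0, 15, delay), trs[, 1:(900 - delay)])
  r <- rol_site(trs, EPOCH_TIMES)
  rs <- rol_site(shifted, EPOCH_TIMES)
  expect_lt(abs((rs$median_ms - r$median_ms) - delay), 4)
})

test_that("site estimates apply the 50% detection rule and median", {
  step_tr <- matrix(rep(as.numeric(EPOCH_TIMES >= 180), 4), 4, byrow = TRUE)
  flat <- matrix(0, 6, 900)
  mixed <- rol_site(rbind(step_tr, flat), EPOCH_TIMES)
  expect_equal(mixed$detection_fraction, 0.4)
  expect_false(mixed$valid)
  # brute-force recount
  expect_equal(mixed$detection_fraction,
               sum(!is.na(mixed$onsets)) / mixed$n_trials)

  all_same <- rol_site(matrix(rep(as.numeric(EPOCH_TIMES >= 180), 5), 5,
                              byrow = TRUE), EPOCH_TIMES)
  expect_true(all_same$valid)
  expect_equal(all_same$median_ms, 152)  # first bin overlapping the 180 ms step
  expect_equal(all_same$median_ms,
               oracle_onset(as.numeric(EPOCH_TIMES >= 180), EPOCH_TIMES, 0))
})

test_that("detection fraction is non-decreasing over the SNR sweep", {
  set.seed(105)
  A <- smooth_noise_trials(60)
  B <- smooth_noise_trials(56)
  grid <- seq(2, 10, by = 2)
  det <- vapply(grid, function(s) {
    rol_site(inject_ramp(A, B, EPOCH_TIMES, s), EPOCH_TIMES)$detection_fraction
  }, 0)
  expect_true(all(diff(det) >= 0))
  expect_gt(det[length(det)], det[1])
})

test_that("gradient analysis recovers correlations and regions", {
  y <- seq(-60, -20, length.out = 10)
  rol <- seq(100, 190, length.out = 10)
  sel <- seq(5, 0.5, length.out = 10)
  g <- gradient_analysis(rol, sel, y)
  expect_equal(g$rol_vs_y$rho, 1)
  expect_equal(g$selectivity_vs_y$rho, -1)
  expect_equal(g$rol_vs_y$n, 10)
  expect_setequal(g$region_means$region, c("posterior", "middle", "anterior"))
  expect_equal(sum(g$region_means$n), 10)

  # referencing subtracts per-subject constants: ranks unchanged within subject
  gr <- gradient_analysis(rol, sel, y, subject = rep("s1", 10),
                          reference = "best_site")
  expect_equal(gr$rol_vs_y$rho, 1)
  expect_error(gradient_analysis(rol[1:3], sel[1:3], y[1:3]), "at least 5")
})

test_that("a planted latency gradient is recovered across seeds", {
  rhos <- vapply(1:20, function(s) {
    set.seed(400 + s)
    y <- runif(30, -70, -30)
    lat <- 120 + 2 * (y + 70)         # 2 ms per mm along y
    rol <- vapply(seq_along(y), function(i) {
      tr <- smooth_noise_trials(20) * 0.25 +
        matrix(rep(0.5 * ramp_shape(EPOCH_TIMES, lat[i], 80), 20), 20,
               byrow = TRUE)
      rol_site(tr, EPOCH_TIMES)$median_ms
    }, 0)
    suppressWarnings(cor(rol, y, method = "spearman"))
  }, 0)
  expect_true(all(rhos > 0.8))
})

test_that("face sites match their nearest task-active sites within tolerance", {
  face <- data.frame(site = c("f1", "f2", "f3"), y = c(-60, -50, -40),
                     rol = c(120, 140, 160))
  task <- data.frame(site = c("t1", "t2"), y = c(-59.5, -49),
                     rol = c(125, 150))
  m <- match_sites(face, task)
  expect_equal(m$n_face, 2)       # f3 has no candidate within 2 mm
  expect_equal(m$pairs$task_site, c("t1", "t2"))

  # identical coordinates and latencies: perfect matching, degenerate test
  same <- data.frame(site = paste0("s", 1:4), y = c(-60, -55, -50, -45),
                     rol = c(110, 120, 130, 140))
  m2 <- match_sites(same, transform(same, site = paste0("t", 1:4)))
  expect_equal(m2$n_face, 4)
  expect_true(all(m2$pairs$dy == 0))
  expect_equal(m2$test$p.value, 1)

  far <- data.frame(site = "t9", y = -70, rol = 100)
  expect_equal(match_sites(face[3, ], far)$n_face, 0)

  # greedy matching equals a brute-force nearest-neighbour search
  set.seed(106)
  f <- data.frame(site = paste0("f", 1:10), y = runif(10, -70, -30),
                  rol = runif(10, 100, 200))
  t2 <- data.frame(site = paste0("t", 1:10), y = runif(10, -70, -30),
                   rol = runif(10, 100, 200))
  m3 <- match_sites(f, t2, tolerance_mm = 5)
  for (i in seq_len(m3$n_face)) {
    fi <- match(m3$pairs$face_site[i], f$site)
    expect_equal(m3$pairs$task_site[i],
                 t2$site[which.min(abs(t2$y - f$y[fi]))])
  }
})
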