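#' Pipeline configuration
#'
#' All stage parameters of the end-to-end synthetic demonstration run, with
#' one master seed from which every random stream is derived. Analysis
#' windows, thresholds, the C grid, the signal-to-noise grid and the
#' random-ensemble size default to the reference values; permutation counts
#' default to reduced desk-scale values (the reference analysis uses
#' 50,000 / 10,000 / 1,000, which remain available by overriding).
#'
#' @param seed Master seed.
#' @param n_sites Number of synthetic sites.
#' @param images_per_category,presentations Task-design size (the reference
#'   design is 25 x 2; the demo default is smaller for runtime).
#' @param fs Sampling rate (Hz).
#' @param freq_step Wavelet frequency step (Hz) for the demo run.
#' @param n_perm_active,n_perm_select,n_perm_decode Permutation counts.
#' @param window,baseline Analysis and baseline windows (ms).
#' @param outer_folds,inner_folds,C_grid Decoding cross-validation settings.
#' @param n_random_models Random-ensemble size (default 499).
#' @param snr_grid Signal-to-noise grid of the ramp semi-simulation.
#' @param rol [rol_params()] for the latency stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_sites = 12, images_per_category = 10,
                            presentations = 2, fs = 1000, freq_step = 10,
                            n_perm_active = 2000, n_perm_select = 1000,
                            n_perm_decode = 100, window = c(150, 500),
                            baseline = c(-100, 0), outer_folds = 5,
                            inner_folds = 0, C_grid = 1,
                            n_random_models = 499,
                            snr_grid = seq(2, 10, by = 0.5),
                            rol = rol_params()) {
  cfg <- list(seed = seed, n_sites = n_sites,
              images_per_category = images_per_category,
              presentations = presentations, fs = fs, freq_step = freq_step,
              n_perm_active = n_perm_active, n_perm_select = n_perm_select,
              n_perm_decode = n_perm_decode, window = window,
              baseline = baseline, outer_folds = outer_folds,
              inner_folds = inner_folds, C_grid = C_grid,
              n_random_models = n_random_models, snr_grid = snr_grid,
              rol = rol)
  class(cfg) <- "pipeline_config"
  cfg
}

# rolling polynomial hash of the deparsed configuration, for provenance
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Planted effects of the demonstration scenario
#'
#' The bundled synthetic scenario: the eight most posterior sites are
#' face-responsive with selectivity decreasing and onset latency increasing
#' toward anterior sites (3 ms per mm along y), and two mid sites respond
#' equally to all categories (task-active). Used by [run_pipeline()].
#'
#' @param layout An [electrode_layout()].
#' @return List of [planted_effect()]s.
#' @export
demo_effects <- function(layout) {
  ord <- order(layout$y)
  n_face <- min(8, nrow(layout) - 2L)
  face_ix <- ord[seq_len(n_face)]
  task_ix <- ord[seq(n_face + 1L, length.out = min(2, nrow(layout) - n_face))]
  y0 <- layout$y[face_ix[1]]
  # amplitudes strong enough that the trial-level onset detector reaches its
  # 50% detection rule on most planted sites; selectivity still falls
  # anteriorly, and the latency gradient is steep enough (3 ms per mm) for
  # median onsets over a 20-trial demo run to resolve the site ordering
  effects <- lapply(seq_along(face_ix), function(k) {
    i <- face_ix[k]
    dy <- layout$y[i] - y0
    planted_effect(layout$name[i], "human_face",
                   amplitude_db = 5 - 0.3 * (k - 1),
                   latency_ms = 110 + 3 * dy)
  })
  c(effects, lapply(task_ix, function(i) {
    planted_effect(layout$name[i], STIM_CATEGORIES, amplitude_db = 3.5,
                   latency_ms = 220)
  }))
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Chains every stage on the bundled synthetic scenario: raw-signal
#' simulation with planted effects, preprocessing to high-frequency
#' broadband power, site classification, decoding over the all-sites and
#' excluding-face-sites models plus the random-subset ensemble and the
#' sparse multiple-kernel model, response-onset-latency gradient analysis,
#' and the stimulation-outcome proportion tests on the bundled counts
#' table. Re-running with the same configuration reproduces every numeric
#' output; all outputs are stamped with the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, results are written as
#'   `results.json` and per-site tables as TSV.
#' @return Nested list of stage results (invisible when writing to disk).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  design <- make_task_design(config$images_per_category,
                             config$presentations, seed = seed)
  layout <- make_electrode_layout(config$n_sites, seed = child_seed(seed, 1L))
  effects <- demo_effects(layout)
  raw <- simulate_raw(design, layout, effects, fs = config$fs,
                      seed = child_seed(seed, 2L))
  bp <- preprocess_recording(raw, design, freq_step = config$freq_step)

  cls <- classify_sites(bp, window = config$window,
                        baseline = config$baseline,
                        n_perm_active = config$n_perm_active,
                        n_perm_select = config$n_perm_select,
                        seed = child_seed(seed, 3L))
  face_sites <- cls$site[cls$human_face_selective | cls$face_selective]
  task_sites <- cls$site[cls$task_active]

  all_sites <- bp$sites
  model1 <- run_site_set_model(bp, all_sites, window = config$window,
                               seed = child_seed(seed, 4L),
                               outer_folds = config$outer_folds,
                               inner_folds = config$inner_folds,
                               C_grid = config$C_grid,
                               n_perm = config$n_perm_decode, model = "I")
  model2_sites <- setdiff(all_sites, cls$site[cls$human_face_selective])
  model2 <- run_site_set_model(bp, model2_sites, window = config$window,
                               seed = child_seed(seed, 4L),
                               outer_folds = config$outer_folds,
                               inner_folds = config$inner_folds,
                               C_grid = config$C_grid, model = "II")

  pool <- c(face_sites, task_sites)
  ens <- NULL
  if (length(face_sites) >= 1 && length(pool) >= 3) {
    size <- min(length(model2_sites), length(pool) - 1L)
    ens <- random_set_models(bp, face_sites, task_sites, size = size,
                             n_models = config$n_random_models,
                             window = config$window,
                             seed = child_seed(seed, 5L),
                             outer_folds = min(config$outer_folds, 2L),
                             C_grid = config$C_grid[1])
  }

  mkl <- NULL
  if (length(pool) >= 2) {
    sk <- site_kernels(bp, pool, window = config$window,
                       seed = child_seed(seed, 4L))
    mkl <- sparse_mkl(sk$kernels, sk$y, C_grid = config$C_grid,
                      inner_folds = config$inner_folds,
                      outer_folds = config$outer_folds,
                      seed = child_seed(seed, 6L))
  }

  # trial-level onsets for human-face trials on responsive sites
  tr <- bp$categories == "human_face"
  rol_tab <- do.call(rbind, lapply(seq_along(bp$sites), function(s) {
    est <- rol_site(matrix(bp$power_raw[tr, s, ], sum(tr)), bp$times,
                    config$rol)
    data.frame(site = bp$sites[s], rol = est$median_ms,
               detection_fraction = est$detection_fraction,
               valid = est$valid, stringsAsFactors = FALSE)
  }))
  rol_tab$y <- layout$y[match(rol_tab$site, layout$name)]
  rol_tab$selectivity <- cls$selectivity[match(rol_tab$site, cls$site)]
  resp <- rol_tab$valid & cls$active[match(rol_tab$site, cls$site)]
  gradient <- NULL
  if (sum(resp) >= 5) {
    gradient <- gradient_analysis(rol_tab$rol[resp],
                                  rol_tab$selectivity[resp],
                                  rol_tab$y[resp])
  }

  counts <- read.delim(system.file("extdata", "stim_counts.tsv",
                                   package = "ecogface"))
  stim <- stim_outcome_tests(counts)
  charge <- charge_per_trial(0.2, 3, 50, 1)

  results <- list(
    provenance = list(seed = seed, config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("ecogface"))),
    n_stimulus_events = sum(design$trial_type != RESPONSE_BLOCK),
    classification = cls,
    model_I = list(balanced_accuracy = model1$balanced_accuracy,
                   p = model1$p),
    model_II = list(balanced_accuracy = model2$balanced_accuracy),
    random_sets = if (!is.null(ens)) list(
      n_models = length(ens$accuracy), rho = ens$rho, rho_p = ens$rho_p,
      mean_accuracy = mean(ens$accuracy)),
    mkl = if (!is.null(mkl)) list(
      balanced_accuracy = mkl$balanced_accuracy,
      sparsity = mkl$sparsity,
      contributions = as.list(mkl$contributions)),
    rol = rol_tab,
    gradient = if (!is.null(gradient)) list(
      rho = gradient$rol_vs_y$rho, p = gradient$rol_vs_y$p,
      n = gradient$rol_vs_y$n),
    stim = stim,
    charge_per_trial_uc = charge
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- results
    json$classification <- NULL
    json$rol <- NULL
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(cls, file.path(out_dir, "site_classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rol_tab, file.path(out_dir, "rol.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(results))
  }
  results
}
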