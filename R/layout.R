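#' Create an electrode layout
#'
#' An electrode layout records, per recording site, a unique label and MNI
#' coordinates in millimetres (the y axis runs posterior to anterior: more
#' negative y = more posterior).
#'
#' @param labels Character vector of unique site labels.
#' @param x,y,z Numeric MNI coordinates (mm); `y` must lie within
#'   \[-90, 40\].
#' @param hemisphere `"L"` or `"R"` per site (recycled).
#' @return A data frame of class `electrode_layout`.
#' @export
electrode_layout <- function(labels, x = 0, y, z = 0, hemisphere = "R") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  if (any(y < -90 | y > 40)) stop("MNI y coordinates must lie within [-90, 40]")
  structure(
    data.frame(name = labels, x = x, y = y, z = z,
               hemisphere = hemisphere, stringsAsFactors = FALSE),
    class = c("electrode_layout", "data.frame")
  )
}

#' Generate a regular synthetic electrode layout
#'
#' Sites are spread along the posterior-anterior (y) axis between `y_range`,
#' emulating a strip of temporal-cortex electrodes, with small random jitter
#' in x and z.
#'
#' @param n_sites Number of sites.
#' @param y_range Extent along the MNI y axis (mm).
#' @param seed Integer seed for the coordinate jitter.
#' @inheritParams electrode_layout
#' @export
make_electrode_layout <- function(n_sites, y_range = c(-70, -20),
                                  hemisphere = "R", seed = 1) {
  stopifnot_scalar_count(n_sites, "n_sites")
  y <- seq(y_range[1], y_range[2], length.out = n_sites)
  with_seed(seed, {
    electrode_layout(
      labels = sprintf("e%02d", seq_len(n_sites)),
      x = round(40 + rnorm(n_sites, sd = 2), 1),
      y = round(y, 1),
      z = round(-20 + rnorm(n_sites, sd = 2), 1),
      hemisphere = hemisphere
    )
  })
}

#' Read and write electrode tables
#'
#' Tab-separated with columns `name`, `x`, `y`, `z`, `hemisphere` (MNI mm).
#' @param layout An `electrode_layout`.
#' @param path File path.
#' @export
write_electrodes_tsv <- function(layout, path) {
  write.table(layout, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_tsv
#' @export
read_electrodes_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  electrode_layout(df$name, df$x, df$y, df$z, df$hemisphere)
}

#' Describe a planted category-selective effect
#'
#' A planted effect endows one synthetic site with amplitude-modulated
#' high-gamma bursts time-locked to its preferred categories: `amplitude_db`
#' is the high-frequency broadband power increase over baseline and
#' `latency_ms` the response onset after stimulus onset.
#'
#' @param site Site label (must exist in the layout given to the simulator).
#' @param categories Preferred categories (subset of [STIM_CATEGORIES]).
#' @param amplitude_db Response amplitude, dB above baseline (>= 0).
#' @param latency_ms Onset latency in ms (>= 0).
#' @param duration_ms Sustained response duration in ms.
#' @param rise_ms Linear rise time of the response envelope in ms.
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(site, categories, amplitude_db, latency_ms = 100,
                           duration_ms = 300, rise_ms = 50) {
  stopifnot(amplitude_db >= 0, latency_ms >= 0)
  bad <- setdiff(categories, STIM_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  structure(list(site = as.character(site), categories = categories,
                 amplitude_db = amplitude_db, latency_ms = latency_ms,
                 duration_ms = duration_ms, rise_ms = rise_ms),
            class = "planted_effect")
}
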