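#' Generate a randomized task design
#'
#' Builds the event table of the fast event-related visual paradigm: each of
#' the eleven stimulus categories contributes `images_per_category` distinct
#' images, each shown `presentations` times, in a fully randomized order.
#' Stimuli are presented for `stim_duration_s` seconds with an inter-stimulus
#' interval of `isi_s` seconds. Attention catch trials ("response blocks", a
#' red "###" pattern requiring a key press) are interleaved after every
#' `response_block_every` stimuli; they occupy time but never count as
#' stimulus events and are excluded from all analyses.
#'
#' The default parameters (25 images per category, two presentations) yield
#' 550 stimulus events, 50 per category.
#'
#' @param images_per_category Number of distinct images per category.
#' @param presentations Number of presentations of each image.
#' @param seed Integer seed; the category order is reproducible under it.
#' @param stim_duration_s Stimulus duration in seconds (default 0.3).
#' @param isi_s Inter-stimulus interval in seconds (default 0.4).
#' @param response_block_every Insert one response block after this many
#'   stimuli; `Inf` disables them.
#' @param start_s Onset of the first event, seconds into the recording.
#'
#' @return An object of class `task_design`: a data frame with columns
#'   `onset` (s), `duration` (s), `trial_type`, plus the design parameters as
#'   attributes.
#' @examples
#' d <- make_task_design(25, 2, seed = 1)
#' sum(d$trial_type != RESPONSE_BLOCK)  # 550
#' @export
make_task_design <- function(images_per_category = 25, presentations = 2,
                             seed = 1, stim_duration_s = 0.3, isi_s = 0.4,
                             response_block_every = 10, start_s = 2) {
  stopifnot_scalar_count(images_per_category, "images_per_category")
  stopifnot_scalar_count(presentations, "presentations")
  n_stim <- length(STIM_CATEGORIES) * images_per_category * presentations
  labels <- rep(rep(STIM_CATEGORIES, each = images_per_category), presentations)
  order <- with_seed(seed, sample.int(n_stim))
  labels <- labels[order]

  # interleave response blocks after every k-th stimulus
  if (is.finite(response_block_every) && response_block_every >= 1) {
    k <- as.integer(response_block_every)
    out <- character(0)
    for (i in seq_len(ceiling(n_stim / k))) {
      chunk <- labels[((i - 1L) * k + 1L):min(i * k, n_stim)]
      out <- c(out, chunk, RESPONSE_BLOCK)
    }
    labels <- out
  }

  step <- stim_duration_s + isi_s
  events <- data.frame(
    onset = start_s + step * (seq_along(labels) - 1L),
    duration = stim_duration_s,
    trial_type = labels,
    stringsAsFactors = FALSE
  )
  stopifnot(all(diff(events$onset) > 0),
            sum(events$trial_type != RESPONSE_BLOCK) == n_stim)
  structure(events,
            class = c("task_design", "data.frame"),
            images_per_category = images_per_category,
            presentations = presentations,
            stim_duration_s = stim_duration_s,
            isi_s = isi_s,
            seed = seed)
}

#' Read and write BIDS-style events tables
#'
#' The task design is serialized as a tab-separated events table with columns
#' `onset`, `duration` and `trial_type` (times in seconds).
#'
#' @param design A `task_design` (or any data frame with those columns).
#' @param path File path.
#' @return `read_events_tsv` returns a `task_design` data frame.
#' @export
write_events_tsv <- function(design, path) {
  write.table(design[, c("onset", "duration", "trial_type")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(df)))
  structure(df[, c("onset", "duration", "trial_type")],
            class = c("task_design", "data.frame"))
}
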