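#' Low-level stimulus image features
#'
#' Control analyses for stimulus sets: mean luminance, with an arbitrary
#' low/high split at 120, and the rotationally averaged spatial-frequency
#' power spectrum.
#'
#' @param image Numeric matrix of pixel luminance values (finite,
#'   non-negative).
#' @return `image_luminance` returns the mean pixel value.
#' @export
image_luminance <- function(image) {
  image <- check_image(image)
  mean(image)
}

#' @rdname image_luminance
#' @param threshold Luminance split point (default 120).
#' @return `luminance_class` returns `"low"` or `"high"`.
#' @export
luminance_class <- function(image, threshold = 120) {
  if (image_luminance(image) < threshold) "low" else "high"
}

#' @rdname image_luminance
#' @return `radial_power_spectrum` returns a data frame with columns
#'   `radius` (spatial-frequency bins, annulus width one bin, 0 = DC) and
#'   `power` (mean 2-D FFT power over each annulus).
#' @export
radial_power_spectrum <- function(image) {
  image <- check_image(image)
  nr <- nrow(image); nc <- ncol(image)
  p <- Mod(fft(image))^2
  # frequency index of each bin, with wrap-around (0 .. n/2)
  fr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  fc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  radius <- round(sqrt(outer(fr^2, fc^2, `+`)))
  prof <- tapply(as.vector(p), as.vector(radius), mean)
  data.frame(radius = as.integer(names(prof)), power = as.numeric(prof),
             row.names = NULL)
}

check_image <- function(image) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (any(image < 0)) stop("luminance values must be non-negative")
  image
}
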