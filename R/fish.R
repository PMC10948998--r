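#' AP expression profile from a single-frame FISH image
#'
#' Takes the middle \code{band_px} pixel rows along the DV axis, divides
#' the AP axis into 1 %EL bins and averages all band pixels within each
#' bin.  The image is assumed oriented with the AP axis along the
#' x (column) axis, anterior at the left; \code{ap_range} re-maps the
#' column extent to %EL when the embryo does not span the full image.
#'
#' @param image 2D grayscale matrix (rows = DV, columns = AP)
#' @param band_px height of the central DV band, px (must not exceed the
#'   image height)
#' @param n_bins number of EL bins
#' @param ap_range %EL spanned by the image columns
#' @return object of class \code{fish_profile}: data.frame with bin_lo,
#'   bin_hi, bin_mid (%EL), raw_mean, corrected (NA until
#'   \code{\link{background_subtract}}), and a \code{background}
#'   attribute
#' @export
fish_profile <- function(image, band_px = 40, n_bins = 100,
                         ap_range = c(0, 100)) {
  stopifnot(is.matrix(image), n_bins >= 1)
  h <- nrow(image)
  if (band_px > h)
    stop("band_px (", band_px, ") exceeds image height (", h, ")")
  top <- floor((h - band_px) / 2)
  band <- image[top + seq_len(band_px), , drop = FALSE]
  el <- ap_range[1] + (seq_len(ncol(image)) - 0.5) / ncol(image) *
    (ap_range[2] - ap_range[1])
  edges <- seq(ap_range[1], ap_range[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(el, edges, rightmost.closed = TRUE), n_bins)
  col_mean <- colMeans(band)
  col_n <- rep(band_px, ncol(image))
  sums <- tapply(col_mean * col_n, factor(bin, levels = seq_len(n_bins)), sum)
  cnts <- tapply(col_n, factor(bin, levels = seq_len(n_bins)), sum)
  out <- data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                    bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
                    raw_mean = as.numeric(sums) / as.numeric(cnts),
                    corrected = NA_real_)
  class(out) <- c("fish_profile", "data.frame")
  attr(out, "background") <- NA_real_
  out
}

#' Background-subtract a FISH profile
#'
#' Subtracts the lowest binned value whose bin center lies in 10-90 %EL
#' (endpoints inclusive) from every bin.  Bins outside that range can go
#' negative; they are reported as-is.
#'
#' @param profile a \code{\link{fish_profile}}
#' @return the profile with \code{corrected = raw_mean - background} and
#'   the \code{background} attribute set
#' @export
background_subtract <- function(profile) {
  in_range <- profile$bin_mid >= 10 & profile$bin_mid <= 90 &
    !is.na(profile$raw_mean)
  if (!any(in_range))
    stop("no bins with centers in 10-90 %EL to estimate background from")
  bg <- min(profile$raw_mean[in_range])
  profile$corrected <- profile$raw_mean - bg
  attr(profile, "background") <- bg
  profile
}

#' @export
plot.fish_profile <- function(x, ...) {
  y <- if (all(is.na(x$corrected))) x$raw_mean else x$corrected
  graphics::plot(x$bin_mid, y, type = "l", xlab = "AP position (%EL)",
                 ylab = "signal (a.u.)", ...)
  invisible(x)
}
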