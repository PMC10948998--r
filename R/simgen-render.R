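#' Render a synthetic two-channel time-lapse stack
#'
#' Produces per-frame (nuclei, MS2) grayscale images from a simulated
#' embryo: the nuclei channel contains filled discs at the nucleus
#' centers; the MS2 channel contains one sub-nuclear Gaussian punctum per
#' transcribing nucleus whose peak equals that nucleus's trace value at
#' that frame (punctum centers are quantized to the pixel grid so the
#' brightest pixel carries the peak).  Frames are already max-projected
#' 2D images; the z max projection of the real-data path is an identity
#' here.
#'
#' @param embryo an \code{\link{embryo_sim}}
#' @param traces its \code{\link{simulate_traces}} table
#' @param nucleus_radius_px nucleus disc radius, px; must be smaller than
#'   half the internuclear spacing (non-overlapping nuclei)
#' @param px_per_um pixel scale
#' @param psf_sigma_px point-spread sigma of the MS2 punctum, px
#' @param background additive constant background, a.u.
#' @param noise_sd additive Gaussian pixel noise, a.u.
#' @param nucleus_value disc intensity in the nuclei channel, a.u.
#' @param seed seed for the pixel noise (deterministic stacks)
#' @return object of class \code{frame_stack}: list with \code{frames}
#'   (per frame, list of \code{nuclei} and \code{ms2} matrices, rows = DV,
#'   columns = AP) and \code{meta} (pixel mapping and frame interval)
#' @export
render_frames <- function(embryo, traces, nucleus_radius_px = 5,
                          px_per_um = 1, psf_sigma_px = 3,
                          background = 0, noise_sd = 0,
                          nucleus_value = 100, seed = embryo$seed) {
  stopifnot(inherits(embryo, "embryo_sim"), px_per_um > 0,
            psf_sigma_px > 0, nucleus_radius_px > 0)
  g <- embryo$geometry
  min_spacing_px <- min(g$ap_spacing, g$dv_spacing) * px_per_um
  if (nrow(embryo$nuclei) > 0 && nucleus_radius_px >= min_spacing_px / 2)
    stop("nucleus_radius_px (", nucleus_radius_px,
         ") must be below half the internuclear spacing (",
         round(min_spacing_px / 2, 2), " px): nuclei would overlap")
  margin <- ceiling(nucleus_radius_px + 4 * psf_sigma_px)
  width <- ceiling(g$ap_length * px_per_um) + 2 * margin
  height <- ceiling(g$dv_window * px_per_um) + 2 * margin
  x_px <- embryo$nuclei$ap_um * px_per_um + margin
  y_px <- (embryo$nuclei$dv_um + g$dv_window / 2) * px_per_um + margin

  frames_id <- if (nrow(traces) > 0) sort(unique(traces$frame))
  else seq(0, floor(g$nc14_duration / g$frame_interval))
  ff <- factor(if (nrow(traces) > 0) traces$frame else integer(0),
               levels = frames_id)
  fl <- split(traces$fluor_ms2, ff)
  st <- split(traces$true_state, ff)
  nid <- split(traces$nucleus_id, ff)

  # static nuclei-channel geometry
  base_nuc <- matrix(background, height, width)
  px_row <- (seq_len(height) - 0.5)
  px_col <- (seq_len(width) - 0.5)
  for (k in seq_len(nrow(embryo$nuclei))) {
    ri <- which(abs(px_row - y_px[k]) <= nucleus_radius_px)
    ci <- which(abs(px_col - x_px[k]) <= nucleus_radius_px)
    dd <- outer((px_row[ri] - y_px[k])^2, (px_col[ci] - x_px[k])^2, "+")
    base_nuc[ri, ci][dd <= nucleus_radius_px^2] <- background + nucleus_value
  }

  win <- ceiling(4 * psf_sigma_px)
  with_seed(seed, {
    frames <- lapply(seq_along(frames_id), function(fi) {
      ord <- order(nid[[fi]])
      f_nuc <- base_nuc
      f_ms2 <- matrix(background, height, width)
      vals <- fl[[fi]][ord]
      on <- st[[fi]][ord] > 0
      for (k in which(on)) {
        i0 <- max(1, min(height, floor(y_px[k]) + 1))
        j0 <- max(1, min(width, floor(x_px[k]) + 1))
        ri <- max(1, i0 - win):min(height, i0 + win)
        ci <- max(1, j0 - win):min(width, j0 + win)
        dd <- outer((ri - i0)^2, (ci - j0)^2, "+")
        f_ms2[ri, ci] <- f_ms2[ri, ci] +
          vals[k] * exp(-dd / (2 * psf_sigma_px^2))
      }
      if (noise_sd > 0) {
        f_nuc <- pmax(f_nuc + matrix(stats::rnorm(height * width, 0, noise_sd),
                                     height, width), 0)
        f_ms2 <- pmax(f_ms2 + matrix(stats::rnorm(height * width, 0, noise_sd),
                                     height, width), 0)
      }
      list(nuclei = f_nuc, ms2 = f_ms2)
    })
    structure(list(
      frames = frames,
      meta = list(channels = c("nuclei", "ms2"),
                  n_frames = length(frames), px_per_um = px_per_um,
                  margin_px = margin, dv_window = g$dv_window,
                  ap_length = g$ap_length,
                  frame_interval = g$frame_interval,
                  nucleus_radius_px = nucleus_radius_px,
                  psf_sigma_px = psf_sigma_px)),
      class = "frame_stack")
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$nuclei)
  cat(sprintf("Frame stack: %d frames x %s channels, %d x %d px\n",
              x$meta$n_frames, paste(x$meta$channels, collapse = "+"),
              d[1], d[2]))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major (frame 1 nuclei, frame 1 ms2, frame 2
#' nuclei, ...).  Pixel values are scaled to [0,1] for the TIFF; the scale
#' factor, channel order and pixel mapping go to \code{<path>.json}.
#'
#' @param stack a \code{\link{render_frames}} stack
#' @param path TIFF file path
#' @return (write) the path, invisibly; (read) a \code{frame_stack}
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- unlist(lapply(stack$frames, function(f)
    lapply(stack$meta$channels, function(ch) f[[ch]])), recursive = FALSE)
  scale <- max(1e-12, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  meta <- stack$meta
  meta$scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  frames <- lapply(seq_len(meta$n_frames), function(fi) {
    fr <- lapply(seq_len(nch), function(ci)
      pages[[(fi - 1) * nch + ci]] * meta$scale)
    names(fr) <- meta$channels
    fr
  })
  structure(list(frames = frames, meta = meta), class = "frame_stack")
}

#' Render a synthetic single-frame gap-gene image
#'
#' A FISH-like 2D image whose columns follow a regulator's AP
#' concentration profile (constant along DV), for exercising the FISH
#' quantification path against a known generating function.
#'
#' @param gene regulator name
#' @param width_px,height_px image size
#' @param t normalized time at which the profile is evaluated
#' @param genotype "wt" or "kr_het"
#' @param regulators regulator set
#' @param scale multiplicative intensity scale, a.u.
#' @param offset additive background, a.u.
#' @param noise_sd Gaussian pixel noise, a.u.
#' @param seed noise seed
#' @return matrix (rows = DV, columns = AP spanning 0-100 %EL)
#' @export
render_gap_image <- function(gene, width_px = 200, height_px = 60,
                             t = 0.5, genotype = "wt",
                             regulators = default_regulators(),
                             scale = 100, offset = 0, noise_sd = 0,
                             seed = 1) {
  el <- (seq_len(width_px) - 0.5) / width_px * 100
  prof <- offset + scale * gap_profile(gene, el, t, genotype, regulators)
  img <- matrix(prof, height_px, width_px, byrow = TRUE)
  if (noise_sd > 0)
    img <- with_seed(seed, pmax(img + matrix(
      stats::rnorm(height_px * width_px, 0, noise_sd),
      height_px, width_px), 0))
  img
}
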