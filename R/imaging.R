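#' Pixel-wise max projection
#'
#' Collapses a z-stack (3D array, z as the third dimension) to a single
#' 2D frame by a pixel-wise maximum; 2D inputs pass through unchanged
#' (synthetic frames are rendered already projected).
#'
#' @param x 2D matrix or 3D array
#' @return 2D matrix
#' @export
max_project <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(length(dim(x)) == 3)
  apply(x, c(1, 2), max)
}

#' Segment nuclei in one frame
#'
#' Gaussian blur, Otsu threshold (on the intensity-normalized image) and
#' connected-component labelling, followed by an area filter.  Blobs that
#' merge below the blur scale may come out as a single label; the
#' generator keeps synthetic nuclei non-overlapping so this simple
#' segmenter suffices, and pre-extracted trace tables are accepted for
#' real data.
#'
#' @param frame 2D grayscale matrix (rows = y, columns = x)
#' @param blur_sigma Gaussian blur sigma, px
#' @param threshold "otsu" or a numeric intensity threshold on the blurred
#'   image (raw scale)
#' @param min_area_px minimum component area, px
#' @return object of class \code{label_mask}: list with \code{labels}
#'   (integer matrix, 0 = background) and \code{centroids} (data.frame
#'   label, x_px, y_px, area); an all-zero image yields 0 labels
#' @export
segment_nuclei <- function(frame, blur_sigma = 2, threshold = "otsu",
                           min_area_px = 10) {
  stopifnot(is.matrix(frame))
  empty <- list(labels = matrix(0L, nrow(frame), ncol(frame)),
                centroids = data.frame(label = integer(0), x_px = numeric(0),
                                       y_px = numeric(0), area = integer(0)))
  class(empty) <- "label_mask"
  mx <- max(frame)
  if (mx <= 0) return(empty)
  sm <- if (blur_sigma > 0) EBImage::gblur(frame, sigma = blur_sigma) else frame
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  else threshold
  mask <- sm > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) return(empty)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab_m <- matrix(0L, nrow(frame), ncol(frame))
  nz <- lab > 0
  lab_m[nz] <- relab[lab[nz]]
  mom <- EBImage::computeFeatures.moment(lab_m)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  out <- list(labels = lab_m,
              centroids = data.frame(label = seq_along(keep),
                                     x_px = mom[, "m.cy"],
                                     y_px = mom[, "m.cx"],
                                     area = areas[keep]))
  class(out) <- "label_mask"
  out
}

#' Link nuclei across frames by greedy nearest-centroid matching
#'
#' Blastoderm nuclei are near-stationary between 61 s frames, so linking
#' is a globally greedy nearest-neighbour assignment per frame pair:
#' closest (track, detection) pairs are linked first; detections farther
#' than \code{max_step_px} from every unmatched track start new tracks.
#' No gap closing: a track that misses a frame ends.
#'
#' @param masks list of \code{\link{segment_nuclei}} masks, one per frame
#' @param max_step_px maximum allowed inter-frame displacement, px
#' @return data.frame with nucleus_id (persistent track id), frame
#'   (1-based), label (per-frame label), x_px, y_px
#' @export
track_nuclei <- function(masks, max_step_px = 5) {
  stopifnot(length(masks) >= 1)
  rows <- list()
  next_id <- 1L
  prev <- NULL  # data.frame: nucleus_id, x_px, y_px
  for (f in seq_along(masks)) {
    det <- masks[[f]]$centroids
    if (nrow(det) == 0) { prev <- NULL; next }
    ids <- rep(NA_integer_, nrow(det))
    if (!is.null(prev) && nrow(prev) > 0) {
      dmat <- outer(prev$x_px, det$x_px, "-")^2 +
        outer(prev$y_px, det$y_px, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        m <- which.min(dmat)
        if (length(m) == 0 || dmat[m] > max_step_px) break
        i <- (m - 1) %% nrow(dmat) + 1
        j <- (m - 1) %/% nrow(dmat) + 1
        ids[j] <- prev$nucleus_id[i]
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    new <- which(is.na(ids))
    if (length(new)) {
      ids[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    rows[[f]] <- data.frame(nucleus_id = ids, frame = f, label = det$label,
                            x_px = det$x_px, y_px = det$y_px)
    prev <- data.frame(nucleus_id = ids, x_px = det$x_px, y_px = det$y_px)
  }
  if (length(rows) == 0)
    return(data.frame(nucleus_id = integer(0), frame = integer(0),
                      label = integer(0), x_px = numeric(0),
                      y_px = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-nucleus MS2 spot signal
#'
#' The MS2 signal of a nucleus is the average of the two brightest pixels
#' within its label (restricted to the nuclear mask); a single-pixel label
#' returns that pixel's value.
#'
#' @param frame 2D signal-channel matrix, same shape as the mask
#' @param mask a \code{\link{segment_nuclei}} mask (or a bare label
#'   matrix)
#' @return named numeric vector of signals, one per label
#' @export
measure_ms2 <- function(frame, mask) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  stopifnot(all(dim(frame) == dim(labels)))
  want <- if (inherits(mask, "label_mask")) mask$centroids$label
  else setdiff(sort(unique(as.integer(labels))), 0L)
  nz <- labels > 0
  vals <- split(frame[nz], labels[nz])
  out <- vapply(as.character(want), function(l) {
    v <- vals[[l]]
    if (is.null(v) || length(v) == 0)
      stop("corrupt mask: label ", l, " has no pixels")
    mean(sort(v, decreasing = TRUE)[seq_len(min(2, length(v)))])
  }, numeric(1))
  names(out) <- want
  out
}

#' Extract per-nucleus traces from a rendered stack
#'
#' Full image path: segments the nuclei channel of every frame, links
#' nuclei over time and measures the MS2 (and PP7, when present) signal
#' per nucleus per frame.  When the stack metadata carries the pixel
#' mapping, trace coordinates are converted back to um / %EL so the table
#' matches the simulator's schema.
#'
#' @param stack a \code{\link{render_frames}} / \code{\link{read_stack}}
#'   stack
#' @param blur_sigma,threshold,min_area_px passed to
#'   \code{\link{segment_nuclei}}
#' @param max_step_px passed to \code{\link{track_nuclei}}
#' @return trace table with nucleus_id, frame, t_seconds, x_px, y_px and
#'   fluor_* columns (plus ap_um/dv_um/el_pct when the mapping is known)
#' @export
quantify_stack <- function(stack, blur_sigma = 2, threshold = "otsu",
                           min_area_px = 10, max_step_px = 5) {
  stopifnot(inherits(stack, "frame_stack"))
  masks <- lapply(stack$frames, function(f)
    segment_nuclei(max_project(f$nuclei), blur_sigma, threshold, min_area_px))
  tracks <- track_nuclei(masks, max_step_px)
  if (nrow(tracks) == 0) return(tracks)
  sig_channels <- setdiff(stack$meta$channels, "nuclei")
  for (ch in sig_channels) {
    col <- paste0("fluor_", ch)
    tracks[[col]] <- NA_real_
    for (f in unique(tracks$frame)) {
      sig <- measure_ms2(max_project(stack$frames[[f]][[ch]]), masks[[f]])
      sel <- tracks$frame == f
      tracks[[col]][sel] <- sig[as.character(tracks$label[sel])]
    }
  }
  m <- stack$meta
  if (!is.null(m$px_per_um)) {
    tracks$ap_um <- (tracks$x_px - m$margin_px) / m$px_per_um
    tracks$dv_um <- (tracks$y_px - m$margin_px) / m$px_per_um -
      m$dv_window / 2
    if (!is.null(m$ap_length)) tracks$el_pct <- 100 * tracks$ap_um / m$ap_length
  }
  if (!is.null(m$frame_interval))
    tracks$t_seconds <- (tracks$frame - 1) * m$frame_interval
  tracks
}
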