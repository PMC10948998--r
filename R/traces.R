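#' Restrict traces to the central DV analysis window
#'
#' Keeps nuclei whose mean DV position lies within a fixed-height window
#' centered on the embryo's DV midline (default 282 um, spanning ~17
#' nuclei), minimizing variation in DV extent across embryos.
#'
#' @param traces trace table (columns nucleus_id, dv_um, ...)
#' @param window_um window height, um
#' @param center window center, um; default the midpoint of the observed
#'   DV range
#' @return the filtered trace table (attributes preserved)
#' @export
select_dv_window <- function(traces, window_um = 282, center = NULL) {
  if (window_um <= 0) stop("window_um must be > 0")
  mean_dv <- tapply(traces$dv_um, traces$nucleus_id, mean)
  if (is.null(center)) center <- mean(range(mean_dv))
  keep_ids <- as.numeric(names(mean_dv))[abs(mean_dv - center) <= window_um / 2]
  out <- traces[traces$nucleus_id %in% keep_ids, , drop = FALSE]
  for (a in c("geometry", "genotype", "seed"))
    attr(out, a) <- attr(traces, a)
  out
}

#' Background estimate from the least-active nuclei
#'
#' Pools the fluorescence values of the nuclei in the lowest decile of
#' per-nucleus mean signal (never/rarely transcribing nuclei) and returns
#' their mean and standard deviation.  Used by \code{\link{normalize_traces}}
#' to set the default active-call threshold (background mean +
#' \code{sd_mult} SDs) and to background-correct the traces.  The default
#' multiplier of 4 keeps the expected number of false active calls well
#' below one per frame on a ~1700-nucleus embryo (3 SDs would give ~2 per
#' frame, enough to corrupt gap-based stripe clustering).
#'
#' @param traces trace table
#' @param channel column name to estimate from
#' @param sd_mult threshold multiplier on the background SD
#' @return list with \code{mean}, \code{sd} and \code{threshold}
#'   (= mean + sd_mult * sd, on the raw scale)
#' @export
estimate_background <- function(traces, channel = "fluor_ms2", sd_mult = 4) {
  v <- traces[[channel]]
  nuc_mean <- tapply(v, traces$nucleus_id, mean)
  cut <- stats::quantile(nuc_mean, 0.1, names = FALSE)
  low_ids <- as.numeric(names(nuc_mean))[nuc_mean <= cut]
  pool <- v[traces$nucleus_id %in% low_ids]
  m <- mean(pool)
  s <- stats::sd(pool)
  if (is.na(s)) s <- 0
  list(mean = m, sd = s, threshold = m + sd_mult * s)
}

#' Normalize traces onto the 100-point NC14 time grid
#'
#' Maps the interval from the end of the 13th mitosis (\code{t_start}) to
#' the beginning of gastrulation (\code{t_end}) onto 100 time points on a
#' 0-1 scale and linearly interpolates each nucleus's fluorescence onto
#' that grid.  Grid points outside a nucleus's observed frames are marked
#' NA (nucleus not present).  With \code{threshold = "auto"} the traces
#' are background-corrected by the estimated background mean (see
#' \code{\link{estimate_background}}) and the active-call threshold is
#' \code{sd_mult} background SDs above zero; a numeric \code{threshold} is
#' applied to the raw signal without correction.
#'
#' @param traces trace table (nucleus_id, t_seconds, el_pct, dv_um,
#'   fluor_ms2, ...)
#' @param t_start,t_end NC14 interval, seconds
#' @param n_points number of grid points
#' @param threshold "auto" or a numeric active-call threshold (a.u.)
#' @param sd_mult background-SD multiplier for the automatic threshold
#' @param channel fluorescence column to analyze
#' @return object of class \code{normalized_traces}: list with
#'   \code{nucleus_id}, \code{el_pct}, \code{dv_um} (per nucleus),
#'   \code{t_norm} (grid), \code{fluor} and \code{active} (nucleus x grid
#'   matrices), \code{threshold}, \code{background}, and carried-over
#'   \code{geometry}/\code{genotype} attributes as fields
#' @export
normalize_traces <- function(traces, t_start = 0,
                             t_end = max(traces$t_seconds),
                             n_points = 100, threshold = "auto",
                             sd_mult = 4, channel = "fluor_ms2") {
  if (t_end <= t_start) stop("t_end must be greater than t_start")
  stopifnot(n_points >= 2)
  in_win <- traces$t_seconds >= t_start & traces$t_seconds <= t_end
  if (length(unique(traces$t_seconds[in_win])) < 2)
    stop("need at least 2 frames inside [t_start, t_end]")
  tr <- traces[in_win, , drop = FALSE]

  bg <- NULL
  if (identical(threshold, "auto")) {
    bg <- estimate_background(tr, channel, sd_mult)
    tr[[channel]] <- tr[[channel]] - bg$mean
    thr <- sd_mult * bg$sd
  } else {
    thr <- threshold
    stopifnot(is.numeric(thr), thr >= 0)
  }

  t_norm <- seq(0, 1, length.out = n_points)
  ids <- sort(unique(tr$nucleus_id))
  idx <- split(seq_len(nrow(tr)), factor(tr$nucleus_id, levels = ids))
  fl <- matrix(NA_real_, length(ids), n_points)
  el <- dv <- numeric(length(ids))
  for (i in seq_along(ids)) {
    rows <- idx[[i]]
    tt <- (tr$t_seconds[rows] - t_start) / (t_end - t_start)
    el[i] <- mean(tr$el_pct[rows])
    dv[i] <- mean(tr$dv_um[rows])
    if (length(rows) >= 2) {
      o <- order(tt)
      fl[i, ] <- stats::approx(tt[o], tr[[channel]][rows][o], xout = t_norm,
                               method = "linear", rule = 1)$y
    } else {
      hit <- which.min(abs(t_norm - tt))
      fl[i, hit] <- tr[[channel]][rows]
    }
  }
  structure(list(nucleus_id = ids, el_pct = el, dv_um = dv,
                 t_norm = t_norm, fluor = fl,
                 active = call_active(fl, thr),
                 threshold = thr, background = bg,
                 geometry = attr(traces, "geometry"),
                 genotype = attr(traces, "genotype")),
            class = "normalized_traces")
}

#' @export
print.normalized_traces <- function(x, ...) {
  cat(sprintf(
    "Normalized traces: %d nuclei x %d time points; threshold %.3g a.u.\n",
    length(x$nucleus_id), length(x$t_norm), x$threshold))
  invisible(x)
}

#' Call transcriptionally active time points
#'
#' A nucleus is active at a time point when its signal strictly exceeds
#' the threshold; a value exactly at the threshold is inactive.  NA
#' (nucleus not present) stays NA.
#'
#' @param fluor numeric vector or matrix of fluorescence values
#' @param threshold active-call threshold, a.u. (>= 0)
#' @return logical of the same shape
#' @export
call_active <- function(fluor, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  fluor > threshold
}

#' Cumulative mRNA output of one trace
#'
#' Approximates mRNA production as the area under the fluorescence
#' trajectory: a trapezoidal integral over normalized time, restricted to
#' the observed (non-NA) support, optionally within a time window.  Units
#' are a.u. x normalized NC14 time.
#'
#' @param fluor fluorescence at the grid points (NA = not present)
#' @param t_norm normalized time grid
#' @param window optional c(lo, hi) in normalized time; only grid points
#'   with lo <= t <= hi contribute
#' @return the integral, or NA if fewer than 2 defined points
#' @export
mrna_output <- function(fluor, t_norm, window = NULL) {
  if (!is.null(window)) {
    keep <- t_norm >= window[1] - 1e-9 & t_norm <= window[2] + 1e-9
    fluor <- fluor[keep]
    t_norm <- t_norm[keep]
  }
  ok <- !is.na(fluor)
  if (sum(ok) < 2) return(NA_real_)
  f <- fluor[ok]
  tt <- t_norm[ok]
  sum(diff(tt) * (f[-1] + f[-length(f)]) / 2)
}

#' Per-nucleus transcription metrics
#'
#' Computes, for every nucleus on the normalized grid: cumulative mRNA
#' output (trapezoidal integral over normalized time), the number of
#' actively transcribing grid points, that duration in minutes, and the
#' average transcriptional amplitude = mRNA output divided by the active
#' duration expressed as a fraction of NC14 (so a constant always-active
#' trace of height c has amplitude c, in fluorescence units).  Amplitude
#' is NA for nuclei never active; output can still be positive from
#' integrated sub-threshold signal.
#'
#' @param nt a \code{\link{normalized_traces}} object
#' @param nc14_duration NC14 duration in seconds (for minutes conversion);
#'   taken from the attached geometry when available
#' @return data.frame with nucleus_id, el_pct, dv_um, mrna_output,
#'   active_duration (grid points), active_minutes, amplitude
#' @export
nucleus_metrics <- function(nt, nc14_duration = NULL) {
  stopifnot(inherits(nt, "normalized_traces"))
  if (is.null(nc14_duration))
    nc14_duration <- nt$geometry$nc14_duration %||% NA_real_
  n_pts <- length(nt$t_norm)
  out <- vapply(seq_along(nt$nucleus_id), function(i)
    mrna_output(nt$fluor[i, ], nt$t_norm), numeric(1))
  dur <- rowSums(nt$active, na.rm = TRUE)
  amp <- ifelse(dur > 0, out / (dur / n_pts), NA_real_)
  data.frame(nucleus_id = nt$nucleus_id, el_pct = nt$el_pct,
             dv_um = nt$dv_um, mrna_output = out,
             active_duration = dur,
             active_minutes = dur / n_pts * nc14_duration / 60,
             amplitude = amp)
}

#' Bin nucleus values along the AP axis
#'
#' Divides the embryo into equal %EL bins (default 50 bins of 2%) and
#' averages the per-nucleus values within each bin.  Bins are half-open
#' [lo, hi); the last bin is closed at 100%EL.  Empty bins have NA mean
#' and count 0.
#'
#' @param values per-nucleus values (NA values are dropped from their bin)
#' @param el_pct per-nucleus AP positions, %EL in [0, 100]
#' @param n_bins number of bins
#' @return data.frame with bin_lo, bin_hi, bin_mid, bin_mean, bin_count
#' @export
bin_profile <- function(values, el_pct, n_bins = 50) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  stopifnot(length(values) == length(el_pct),
            all(el_pct >= 0 & el_pct <= 100))
  edges <- seq(0, 100, length.out = n_bins + 1)
  bin <- pmin(findInterval(el_pct, edges, rightmost.closed = TRUE), n_bins)
  keep <- !is.na(values)
  sums <- tapply(values[keep], factor(bin[keep], levels = seq_len(n_bins)), sum)
  cnts <- tapply(rep(1, sum(keep)), factor(bin[keep], levels = seq_len(n_bins)),
                 sum)
  cnts[is.na(cnts)] <- 0
  data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
             bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
             bin_mean = as.numeric(sums) / ifelse(cnts > 0, cnts, NA),
             bin_count = as.integer(cnts))
}
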