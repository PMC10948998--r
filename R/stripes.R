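#' Define mature stripes from the last pre-gastrulation frame
#'
#' Nuclei transcribing in the last frame before gastrulation anchor the
#' mature stripes.  Their AP positions are clustered by one-dimensional
#' gap splitting: sorted positions are cut wherever the gap between
#' consecutive active nuclei exceeds \code{gap_min}; clusters with fewer
#' than \code{min_cluster} nuclei are discarded; surviving clusters are
#' numbered anterior to posterior.  Each stripe's domain runs from its
#' anterior border to the next stripe's anterior border (half-open); the
#' last stripe's domain runs to the posterior end (100 %EL, closed).
#'
#' @param el_active AP positions (%EL) of the active nuclei at the last
#'   frame
#' @param gap_min split threshold, %EL (default 2 internuclear spacings
#'   under the default geometry)
#' @param min_cluster minimum nuclei per stripe
#' @return data.frame with stripe_id, anterior, posterior (extreme active
#'   nuclei of the cluster), n_nuclei, domain_start, domain_end
#' @export
define_mature_stripes <- function(el_active, gap_min = 2, min_cluster = 3) {
  el_active <- el_active[!is.na(el_active)]
  if (length(el_active) == 0) stop("no mature stripes: no active nuclei")
  x <- sort(el_active)
  cl <- cumsum(c(0, diff(x) > gap_min))
  sizes <- tapply(rep(1, length(x)), cl, sum)
  keep <- names(sizes)[sizes >= min_cluster]
  if (length(keep) == 0) stop("no mature stripes: all clusters below min_cluster")
  ant <- tapply(x, cl, min)[keep]
  post <- tapply(x, cl, max)[keep]
  o <- order(ant)
  d <- data.frame(stripe_id = seq_along(keep),
                  anterior = as.numeric(ant[o]),
                  posterior = as.numeric(post[o]),
                  n_nuclei = as.integer(sizes[keep][o]))
  d$domain_start <- d$anterior
  d$domain_end <- c(d$anterior[-1], 100)
  d
}

#' Assign nuclei to stripe domains
#'
#' Every nucleus whose AP position falls inside a stripe domain interval
#' [domain_start, domain_end) gets that stripe id (the last domain is
#' closed at 100 %EL); nuclei anterior to stripe 1's border get NA.
#'
#' @param domains output of \code{\link{define_mature_stripes}}
#' @param el_pct nucleus AP positions, %EL
#' @return integer stripe id per nucleus (NA outside all domains)
#' @export
assign_nuclei_to_stripes <- function(domains, el_pct) {
  o <- order(domains$domain_start)
  starts <- domains$domain_start[o]
  ends <- domains$domain_end[o]
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("overlapping stripe domains")
  out <- rep(NA_integer_, length(el_pct))
  for (k in seq_len(nrow(domains))) {
    last <- k == nrow(domains)
    hit <- el_pct >= starts[k] & (if (last) el_pct <= ends[k]
                                  else el_pct < ends[k])
    out[hit] <- domains$stripe_id[k]
  }
  out
}

#' Track stripe boundaries over time via DV sections
#'
#' The DV window is divided into \code{n_sections} equal-height sections.
#' At each normalized time point and for each stripe, the most anterior
#' and most posterior transcriptionally active nuclei of that stripe's
#' domain are marked per section; the boundary position is the mean over
#' the sections that contain active nuclei (empty sections are omitted;
#' a time point with no active section is NA).  Width is posterior minus
#' anterior, reported in %EL and in nuclei; position is the midpoint.
#'
#' @param nt a \code{\link{normalized_traces}} object
#' @param domains output of \code{\link{define_mature_stripes}}
#' @param n_sections number of DV sections
#' @param el_per_nucleus %EL per internuclear spacing, for the nuclei
#'   conversion (from the attached geometry when available)
#' @param dv_range DV window range, um; default the observed range
#' @return data.frame of class \code{boundary_track} with stripe_id,
#'   t_norm, anterior, posterior, width_el, width_nuclei, position,
#'   n_active
#' @export
boundary_track <- function(nt, domains, n_sections = 5,
                           el_per_nucleus = NULL, dv_range = NULL) {
  stopifnot(inherits(nt, "normalized_traces"))
  if (n_sections < 1) stop("n_sections must be >= 1")
  if (is.null(el_per_nucleus))
    el_per_nucleus <- nt$geometry$el_per_nucleus %||% 1
  if (is.null(dv_range)) dv_range <- range(nt$dv_um)
  sec_edges <- seq(dv_range[1], dv_range[2], length.out = n_sections + 1)
  section <- pmin(pmax(findInterval(nt$dv_um, sec_edges,
                                    rightmost.closed = TRUE), 1), n_sections)
  stripe_of <- assign_nuclei_to_stripes(domains, nt$el_pct)
  n_t <- length(nt$t_norm)

  rows <- vector("list", nrow(domains))
  for (k in seq_len(nrow(domains))) {
    sid <- domains$stripe_id[k]
    member <- which(!is.na(stripe_of) & stripe_of == sid)
    ant <- post <- rep(NA_real_, n_t)
    n_act <- integer(n_t)
    for (ti in seq_len(n_t)) {
      act <- member[which(nt$active[member, ti])]
      n_act[ti] <- length(act)
      if (length(act) == 0) next
      a_sec <- tapply(nt$el_pct[act], section[act], min)
      p_sec <- tapply(nt$el_pct[act], section[act], max)
      ant[ti] <- mean(a_sec)
      post[ti] <- mean(p_sec)
    }
    rows[[k]] <- data.frame(stripe_id = sid, t_norm = nt$t_norm,
                            anterior = ant, posterior = post,
                            width_el = post - ant,
                            width_nuclei = (post - ant) / el_per_nucleus,
                            position = (ant + post) / 2,
                            n_active = n_act)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("boundary_track", "data.frame")
  attr(out, "el_per_nucleus") <- el_per_nucleus
  out
}

#' @export
plot.boundary_track <- function(x, stripes = unique(x$stripe_id), ...) {
  graphics::plot(NA, xlim = range(x$t_norm), ylim = range(c(x$anterior,
                 x$posterior), na.rm = TRUE), xlab = "normalized NC14 time",
                 ylab = "AP position (%EL)", ...)
  for (s in stripes) {
    d <- x[x$stripe_id == s, ]
    graphics::lines(d$t_norm, d$anterior, col = s)
    graphics::lines(d$t_norm, d$posterior, col = s, lty = 2)
  }
  invisible(x)
}

#' Time-window summary of stripe position and width
#'
#' Averages boundary-track position and width over the normalized-time
#' window (default grid points 0.80-0.90, the late-NC14 window used to
#' quantify mature stripe differences).
#'
#' @param bt a \code{\link{boundary_track}}
#' @param window c(lo, hi) in normalized time, inclusive
#' @return data.frame with stripe_id, position, width_el, width_nuclei
#'   (NA when the stripe has no defined values in the window)
#' @export
summarize_window <- function(bt, window = c(0.80, 0.90)) {
  stopifnot(window[1] >= 0, window[2] <= 1, window[1] <= window[2])
  sel <- bt$t_norm >= window[1] - 1e-9 & bt$t_norm <= window[2] + 1e-9
  d <- bt[sel, , drop = FALSE]
  agg <- function(v) tapply(v, d$stripe_id, function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  data.frame(stripe_id = as.integer(names(agg(d$position))),
             position = as.numeric(agg(d$position)),
             width_el = as.numeric(agg(d$width_el)),
             width_nuclei = as.numeric(agg(d$width_nuclei)),
             row.names = NULL)
}

#' Transient stripe-2 posterior expansion
#'
#' The expansion is the largest difference between the cohort-mean
#' heterozygote and wild-type stripe widths over the mid-NC14 window,
#' converted to nuclei.
#'
#' @param wt_tracks,het_tracks lists of \code{\link{boundary_track}}s (one
#'   per embryo)
#' @param stripe_id stripe to compare
#' @param window mid-NC14 window in normalized time
#' @param el_per_nucleus %EL per internuclear spacing
#' @return maximum width difference (het - wt), nuclei
#' @export
stripe2_expansion <- function(wt_tracks, het_tracks, stripe_id = 2,
                              window = c(0.40, 0.70), el_per_nucleus = NULL) {
  if (length(wt_tracks) == 0 || length(het_tracks) == 0)
    stop("both cohorts must be nonempty")
  if (is.null(el_per_nucleus))
    el_per_nucleus <- attr(wt_tracks[[1]], "el_per_nucleus") %||% 1
  cohort_width <- function(tracks) {
    w <- vapply(tracks, function(bt) {
      d <- bt[bt$stripe_id == stripe_id, ]
      d$width_el[order(d$t_norm)]
    }, numeric(sum(wt_tracks[[1]]$stripe_id == stripe_id)))
    rowMeans(w, na.rm = TRUE)
  }
  t_grid <- sort(wt_tracks[[1]]$t_norm[wt_tracks[[1]]$stripe_id == stripe_id])
  diff_w <- cohort_width(het_tracks) - cohort_width(wt_tracks)
  sel <- t_grid >= window[1] - 1e-9 & t_grid <= window[2] + 1e-9
  max(diff_w[sel], na.rm = TRUE) / el_per_nucleus
}

#' Stripe activation kinetics
#'
#' Fraction of a stripe domain's nuclei transcribing at each normalized
#' time point.
#'
#' @param nt a \code{\link{normalized_traces}} object
#' @param domains output of \code{\link{define_mature_stripes}}
#' @return data.frame of class \code{kinetics_curve} with stripe_id,
#'   t_norm, n_active, frac_active
#' @export
activation_kinetics <- function(nt, domains) {
  stopifnot(inherits(nt, "normalized_traces"))
  stripe_of <- assign_nuclei_to_stripes(domains, nt$el_pct)
  rows <- lapply(seq_len(nrow(domains)), function(k) {
    sid <- domains$stripe_id[k]
    member <- which(!is.na(stripe_of) & stripe_of == sid)
    if (length(member) == 0) stop("stripe ", sid, " has no member nuclei")
    n_act <- colSums(nt$active[member, , drop = FALSE], na.rm = TRUE)
    data.frame(stripe_id = sid, t_norm = nt$t_norm,
               n_active = as.integer(n_act),
               frac_active = n_act / length(member))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("kinetics_curve", "data.frame")
  out
}

#' Activation onset time of a kinetics curve
#'
#' @param kin a \code{\link{activation_kinetics}} curve
#' @param stripe_id stripe
#' @param onset_frac fraction of domain nuclei that must be active
#' @return first normalized time with frac_active >= onset_frac, or NA
#' @export
onset_time <- function(kin, stripe_id, onset_frac = 0.10) {
  d <- kin[kin$stripe_id == stripe_id, ]
  d <- d[order(d$t_norm), ]
  hit <- which(d$frac_active >= onset_frac)
  if (length(hit) == 0) return(NA_real_)
  d$t_norm[hit[1]]
}

#' Activation onset delay between two kinetics curves
#'
#' @param curve_ref,curve_cmp kinetics curves (e.g. wild type and
#'   heterozygote)
#' @param stripe_id stripe
#' @param nc14_duration NC14 duration, seconds
#' @param onset_frac onset-crossing fraction
#' @return onset(curve_cmp) - onset(curve_ref), minutes; NA if either
#'   never crosses
#' @export
onset_delay <- function(curve_ref, curve_cmp, stripe_id,
                        nc14_duration = 3050, onset_frac = 0.10) {
  a <- onset_time(curve_ref, stripe_id, onset_frac)
  b <- onset_time(curve_cmp, stripe_id, onset_frac)
  (b - a) * nc14_duration / 60
}

#' Distance between two stripes over time
#'
#' Midpoint-to-midpoint AP distance per normalized time point.
#'
#' @param bt a \code{\link{boundary_track}}
#' @param stripe_a,stripe_b stripe ids (distance = position_b - position_a)
#' @return data.frame with t_norm, distance (%EL; NA where either stripe
#'   is undefined)
#' @export
interstripe_distance <- function(bt, stripe_a, stripe_b) {
  a <- bt[bt$stripe_id == stripe_a, ]
  b <- bt[bt$stripe_id == stripe_b, ]
  a <- a[order(a$t_norm), ]
  b <- b[order(b$t_norm), ]
  stopifnot(nrow(a) == nrow(b))
  data.frame(t_norm = a$t_norm, distance = b$position - a$position)
}

#' Aligned per-stripe mRNA-output profile
#'
#' Pools a stripe's nuclei across embryos after re-origining each embryo's
#' AP coordinate at its anteriormost stripe nucleus, bins the per-nucleus
#' mRNA output (integrated over a mid-NC14 time window) into 1 %EL bins,
#' and drops bins whose pooled nucleus count is below \code{min_n}.
#'
#' @param nuclei data.frame with columns embryo_id, el_pct, output (one
#'   row per nucleus; output already integrated over the desired window)
#' @param bin_el bin width, %EL
#' @param min_n minimum pooled nuclei per kept bin
#' @return data.frame with rel_el (bin left edge, %EL from the
#'   anteriormost nucleus), mean_output, n
#' @export
aligned_output_profile <- function(nuclei, bin_el = 1, min_n = 10) {
  if (nrow(nuclei) == 0) stop("empty stripe: no nuclei to align")
  rel <- unlist(lapply(split(nuclei$el_pct, nuclei$embryo_id),
                       function(e) e - min(e)), use.names = FALSE)
  ord <- order(nuclei$embryo_id)
  out <- nuclei$output[ord]
  bin <- floor(rel / bin_el)
  m <- tapply(out, bin, mean)
  n <- tapply(rep(1, length(out)), bin, sum)
  keep <- n >= min_n
  data.frame(rel_el = as.numeric(names(m)[keep]) * bin_el,
             mean_output = as.numeric(m[keep]),
             n = as.integer(n[keep]), row.names = NULL)
}

#' Threshold-crossing boundaries of a binned spatial profile
#'
#' For broad domains measured as binned profiles (e.g. gap-gene reporter
#' signal), the domain boundaries are where the binned signal rises above
#' a threshold: the anterior boundary is the left edge of the first bin
#' above threshold and the posterior boundary the right edge of the last
#' (contiguity between them is not required).
#'
#' @param profile a \code{\link{bin_profile}} data.frame
#' @param threshold signal threshold, a.u.
#' @return c(anterior, posterior) in %EL, or c(NA, NA) if no bin exceeds
#'   the threshold
#' @export
profile_boundaries_by_threshold <- function(profile, threshold) {
  above <- which(!is.na(profile$bin_mean) & profile$bin_mean > threshold)
  if (length(above) == 0) return(c(anterior = NA_real_, posterior = NA_real_))
  c(anterior = profile$bin_lo[min(above)],
    posterior = profile$bin_hi[max(above)])
}
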