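#' Classify embryo genotype from the PP7 reporter channel
#'
#' Wild-type embryos carry the posterior PP7 reporter; Kr heterozygotes do
#' not.  An embryo is called wild type when at least \code{min_frac} of the
#' nuclei in the posterior window ever exceed the PP7 threshold, and
#' heterozygous otherwise.
#'
#' @param traces trace table with a fluor_pp7 column
#' @param posterior_window AP window examined, %EL
#' @param threshold PP7 intensity threshold, a.u.
#' @param min_frac minimum fraction of reporter-positive nuclei
#' @return "wt", "kr_het", or "unknown" when no nuclei lie in the window
#' @export
classify_genotype <- function(traces, posterior_window = c(70, 100),
                              threshold = 25, min_frac = 0.2) {
  if (!"fluor_pp7" %in% names(traces)) stop("traces carry no PP7 channel")
  sub <- traces[traces$el_pct >= posterior_window[1] &
                traces$el_pct <= posterior_window[2], , drop = FALSE]
  if (nrow(sub) == 0) return("unknown")
  ever <- tapply(sub$fluor_pp7, sub$nucleus_id, function(v) any(v > threshold))
  if (mean(ever) >= min_frac) "wt" else "kr_het"
}

#' Coefficient-of-variation profile across embryos
#'
#' For each AP bin, the coefficient of variation of the embryo-level
#' per-bin values (one value per embryo per bin): sample standard
#' deviation divided by the mean.  NA where fewer than 2 embryos
#' contribute or the mean is not positive.
#'
#' @param profiles either a list of \code{\link{bin_profile}} data.frames
#'   (one per embryo, identical binning) or a numeric matrix with one row
#'   per embryo and one column per bin
#' @param bin_mid bin centers (%EL); taken from the first profile when a
#'   list is supplied
#' @return data.frame with bin_mid, cv, n_embryos
#' @export
cv_profile <- function(profiles, bin_mid = NULL) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    if (length(profiles) < 2) stop("cv_profile needs at least 2 embryos")
    if (is.null(bin_mid)) bin_mid <- profiles[[1]]$bin_mid
    mat <- do.call(rbind, lapply(profiles, function(p) p$bin_mean))
  } else {
    mat <- profiles
    if (nrow(mat) < 2) stop("cv_profile needs at least 2 embryos")
    if (is.null(bin_mid)) bin_mid <- seq_len(ncol(mat))
  }
  n <- colSums(!is.na(mat))
  m <- colMeans(mat, na.rm = TRUE)
  s <- apply(mat, 2, stats::sd, na.rm = TRUE)
  cv <- ifelse(n >= 2 & !is.na(m) & m > 0, s / m, NA_real_)
  data.frame(bin_mid = bin_mid, cv = cv, n_embryos = n)
}

#' Analyze one embryo's traces end to end
#'
#' Applies the standard per-embryo pipeline: DV-window selection, time
#' normalization with automatic background threshold, mature-stripe
#' definition at the last frame, boundary tracking over five DV sections,
#' activation kinetics, per-nucleus metrics, and a 50-bin cumulative
#' mRNA-output profile.  Genotype is classified from the PP7 channel when
#' present.
#'
#' @param traces trace table (from \code{\link{simulate_traces}},
#'   \code{\link{quantify_stack}} or \code{\link{read_traces}})
#' @param dv_window_um DV analysis window, um
#' @param threshold active-call threshold ("auto" or numeric)
#' @param n_time_points normalized time grid size
#' @param n_bins AP bins for the output profile
#' @param n_sections DV boundary sections
#' @param gap_min,min_cluster mature-stripe clustering parameters
#'   (\code{gap_min} defaults to 2 internuclear spacings)
#' @param el_per_nucleus %EL per nucleus column; from the attached
#'   geometry when available
#' @param nc14_duration NC14 duration, seconds
#' @return object of class \code{embryo_record}: list with genotype, nt,
#'   domains, bt (boundary track), kinetics, metrics, profile, threshold
#' @export
analyze_embryo <- function(traces, dv_window_um = 282, threshold = "auto",
                           n_time_points = 100, n_bins = 50, n_sections = 5,
                           gap_min = NULL, min_cluster = 3,
                           el_per_nucleus = NULL, nc14_duration = NULL) {
  g <- attr(traces, "geometry")
  if (is.null(el_per_nucleus)) el_per_nucleus <- g$el_per_nucleus %||% 1
  if (is.null(nc14_duration))
    nc14_duration <- g$nc14_duration %||% max(traces$t_seconds)
  if (is.null(gap_min)) gap_min <- 2 * el_per_nucleus

  genotype <- if ("fluor_pp7" %in% names(traces))
    classify_genotype(traces) else "unknown"
  tr <- select_dv_window(traces, window_um = dv_window_um)
  nt <- normalize_traces(tr, t_end = nc14_duration,
                         n_points = n_time_points, threshold = threshold)
  last <- ncol(nt$active)
  domains <- define_mature_stripes(nt$el_pct[which(nt$active[, last])],
                                   gap_min = gap_min,
                                   min_cluster = min_cluster)
  bt <- boundary_track(nt, domains, n_sections = n_sections,
                       el_per_nucleus = el_per_nucleus)
  kin <- activation_kinetics(nt, domains)
  metrics <- nucleus_metrics(nt, nc14_duration = nc14_duration)
  metrics$stripe_id <- assign_nuclei_to_stripes(domains, metrics$el_pct)
  profile <- bin_profile(metrics$mrna_output, metrics$el_pct, n_bins = n_bins)
  structure(list(genotype = genotype, nt = nt, domains = domains,
                 bt = bt, kinetics = kin, metrics = metrics,
                 profile = profile, threshold = nt$threshold,
                 el_per_nucleus = el_per_nucleus,
                 nc14_duration = nc14_duration),
            class = "embryo_record")
}

#' @export
print.embryo_record <- function(x, ...) {
  cat(sprintf("Embryo record (%s): %d nuclei, %d stripes, threshold %.3g\n",
              x$genotype, length(x$nt$nucleus_id), nrow(x$domains),
              x$threshold))
  invisible(x)
}

#' Compare wild-type and Kr-heterozygote cohorts
#'
#' Per stripe: mean +/- s.e.m. (across embryos) of late-NC14 width and
#' position, the width/position differences in nuclei, the activation
#' onset delay, and a two-sample Student's t-test (pooled variance) on the
#' pooled per-nucleus cumulative mRNA output of ever-active domain nuclei.
#' Also reports the transient stripe-2 expansion metric.
#'
#' @param wt_records,het_records lists of \code{\link{analyze_embryo}}
#'   records
#' @param summary_window late-NC14 window for width/position
#' @param expansion_window mid-NC14 window for the stripe-2 expansion
#' @param onset_frac kinetics onset fraction
#' @param welch use Welch's t-test instead of the pooled-variance form
#' @return object of class \code{genotype_comparison}: list with
#'   \code{stripes} (per-stripe data.frame) and
#'   \code{stripe2_expansion_nuclei}
#' @export
compare_genotypes <- function(wt_records, het_records,
                              summary_window = c(0.80, 0.90),
                              expansion_window = c(0.40, 0.70),
                              onset_frac = 0.10, welch = FALSE) {
  if (length(wt_records) < 1 || length(het_records) < 1)
    stop("both cohorts must contain at least one embryo")
  epn <- wt_records[[1]]$el_per_nucleus
  nc14 <- wt_records[[1]]$nc14_duration
  n_stripes <- min(vapply(c(wt_records, het_records),
                          function(r) nrow(r$domains), integer(1)))

  summ <- function(recs) lapply(recs, function(r)
    summarize_window(r$bt, summary_window))
  sw <- summ(wt_records); sh <- summ(het_records)
  pick <- function(lst, sid, col) vapply(lst, function(s) {
    v <- s[[col]][s$stripe_id == sid]
    if (length(v) == 0) NA_real_ else v
  }, numeric(1))
  sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  # per-nucleus outputs of ever-active nuclei within the mature stripe
  # proper (its anterior-posterior extent at the last frame), not the whole
  # inter-stripe domain
  pooled_output <- function(recs, sid) unlist(lapply(recs, function(r) {
    m <- r$metrics
    d <- r$domains[r$domains$stripe_id == sid, ]
    if (nrow(d) == 0) return(numeric(0))
    m$mrna_output[m$el_pct >= d$anterior & m$el_pct <= d$posterior &
                  m$active_duration > 0]
  }))
  mean_onset <- function(recs, sid) mean(vapply(recs, function(r)
    onset_time(r$kinetics, sid, onset_frac), numeric(1)), na.rm = TRUE)

  rows <- lapply(seq_len(n_stripes), function(sid) {
    ww <- pick(sw, sid, "width_nuclei"); wh <- pick(sh, sid, "width_nuclei")
    pw <- pick(sw, sid, "position"); ph <- pick(sh, sid, "position")
    ow <- pooled_output(wt_records, sid); oh <- pooled_output(het_records, sid)
    tt <- if (length(ow) >= 2 && length(oh) >= 2)
      stats::t.test(ow, oh, var.equal = !welch) else list(statistic = NA,
                                                          p.value = NA)
    on_w <- mean_onset(wt_records, sid); on_h <- mean_onset(het_records, sid)
    data.frame(
      stripe_id = sid,
      width_wt = mean(ww, na.rm = TRUE), width_wt_sem = sem(ww),
      width_het = mean(wh, na.rm = TRUE), width_het_sem = sem(wh),
      width_deficit_nuclei = mean(ww, na.rm = TRUE) - mean(wh, na.rm = TRUE),
      position_wt = mean(pw, na.rm = TRUE), position_wt_sem = sem(pw),
      position_het = mean(ph, na.rm = TRUE), position_het_sem = sem(ph),
      anterior_shift_nuclei = (mean(pw, na.rm = TRUE) -
                               mean(ph, na.rm = TRUE)) / epn,
      onset_wt = on_w, onset_het = on_h,
      onset_delay_min = (on_h - on_w) * nc14 / 60,
      n_nuclei_wt = length(ow), n_nuclei_het = length(oh),
      output_t = as.numeric(tt$statistic), output_p = tt$p.value)
  })
  stripes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  exp2 <- stripe2_expansion(lapply(wt_records, `[[`, "bt"),
                            lapply(het_records, `[[`, "bt"),
                            window = expansion_window, el_per_nucleus = epn)
  structure(list(stripes = stripes, stripe2_expansion_nuclei = exp2,
                 n_wt = length(wt_records), n_het = length(het_records)),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("Genotype comparison: %d wild-type vs %d Kr-het embryos\n",
              x$n_wt, x$n_het))
  cat(sprintf("Transient stripe-2 expansion: %.2f nuclei\n",
              x$stripe2_expansion_nuclei))
  d <- x$stripes
  for (i in seq_len(nrow(d))) {
    cat(sprintf(
      "stripe %d: width %.2f vs %.2f nuclei (deficit %.2f); shift %.2f nuclei; delay %.1f min; t=%.1f p=%.3g\n",
      d$stripe_id[i], d$width_wt[i], d$width_het[i],
      d$width_deficit_nuclei[i], d$anterior_shift_nuclei[i],
      d$onset_delay_min[i], d$output_t[i], d$output_p[i]))
  }
  invisible(x)
}
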