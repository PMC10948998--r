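#' Construct a synthetic embryo
#'
#' Bundles a nucleus lattice, stripe rules, regulator fields and a genotype
#' preset into a simulation-ready object.  Wild-type embryos carry the
#' posterior PP7 reporter (emulating the reporter used to distinguish
#' genotypes at the microscope); Kr heterozygotes do not.
#'
#' @param genotype "wt" or "kr_het"
#' @param geometry an \code{\link{embryo_geometry}}
#' @param rules stripe rules, see \code{\link{default_stripe_rules}}
#' @param regulators regulator set, see \code{\link{default_regulators}}
#' @param seed integer seed; a fixed seed gives bit-identical traces
#' @param noise_sd additive Gaussian measurement noise, a.u.
#' @param baseline additive fluorescence baseline (camera offset /
#'   autofluorescence), a.u.; keeps the clipped noise floor approximately
#'   Gaussian so the background estimator is unbiased
#' @param stripe_jitter_el half-range of the per-embryo uniform rigid
#'   displacement of each stripe, %EL (embryo-to-embryo variability)
#' @param bursting if FALSE, promoters are deterministically ON whenever
#'   eligible (step-edged, noise-free recovery surface); if TRUE, two-state
#'   telegraph switching with exponential waiting times
#' @param engine "direct": stripes are ON-eligible inside their planted
#'   (genotype-adjusted) edges; "regulators": burst propensity computed
#'   from the regulator fields via \code{\link{stripe_rate}}
#' @param pp7_domain posterior reporter domain, %EL
#' @param pp7_amplitude,pp7_onset PP7 reporter signal (a.u.) and onset
#'   (normalized time)
#' @return an object of class \code{embryo_sim}
#' @export
embryo_sim <- function(genotype = c("wt", "kr_het"),
                       geometry = embryo_geometry(),
                       rules = default_stripe_rules(),
                       regulators = default_regulators(),
                       seed = 1, noise_sd = 5, baseline = 10,
                       stripe_jitter_el = 0.5, bursting = TRUE,
                       engine = c("direct", "regulators"),
                       pp7_domain = c(70, 96), pp7_amplitude = 80,
                       pp7_onset = 0.1) {
  genotype <- match.arg(genotype)
  engine <- match.arg(engine)
  stopifnot(inherits(geometry, "embryo_geometry"), noise_sd >= 0,
            baseline >= 0, stripe_jitter_el >= 0)
  nuc <- nucleus_lattice(geometry)
  structure(list(genotype = genotype, geometry = geometry,
                 nuclei = nuc, rules = rules, regulators = regulators,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 baseline = baseline, stripe_jitter_el = stripe_jitter_el,
                 bursting = bursting, engine = engine,
                 pp7_domain = pp7_domain, pp7_amplitude = pp7_amplitude,
                 pp7_onset = pp7_onset,
                 has_pp7_reporter = genotype == "wt"),
            class = "embryo_sim")
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("Synthetic embryo (%s), %d nuclei, %d stripes, seed %d\n",
              x$genotype, nrow(x$nuclei), length(x$rules), x$seed))
  print(x$geometry)
  invisible(x)
}

#' Planted ground truth of a synthetic embryo
#'
#' The effective mature stripe edges (at the reference time, without the
#' transient stripe-2 term) and onset times actually used by
#' \code{\link{simulate_traces}}, i.e. after genotype deltas but before
#' grid quantization and jitter.
#'
#' @param embryo an \code{\link{embryo_sim}}
#' @return data.frame with stripe_id, anterior, posterior, width_el,
#'   width_nuclei, position, onset_time, loading_amplitude
#' @export
planted_truth <- function(embryo) {
  g <- embryo$geometry
  rows <- lapply(embryo$rules, function(r) {
    e <- stripe_edges(r, t = 1, embryo$genotype, g$el_per_nucleus)
    onset <- r$onset_time +
      if (embryo$genotype == "kr_het")
        r$genotype_deltas$onset_delay_s / g$nc14_duration else 0
    amp <- r$loading_amplitude *
      if (embryo$genotype == "kr_het") r$genotype_deltas$amplitude_factor else 1
    data.frame(stripe_id = r$stripe_id, anterior = e[1], posterior = e[2],
               width_el = e[2] - e[1],
               width_nuclei = (e[2] - e[1]) / g$el_per_nucleus,
               position = mean(e), onset_time = onset,
               loading_amplitude = amp)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate per-nucleus fluorescence traces
#'
#' Runs the two-state telegraph model on every nucleus of the lattice over
#' the NC14 frame grid.  Promoter states are sampled exactly at frame times
#' from the closed-form two-state transition probabilities with
#' piecewise-constant rates per frame interval (exponential waiting times).
#' Fluorescence is \code{baseline + loading_amplitude} while ON plus
#' Gaussian noise, clipped at zero.  The PP7 channel carries the posterior
#' reporter signal in wild-type embryos only, plus the same noise floor.
#'
#' @param embryo an \code{\link{embryo_sim}}
#' @return data.frame (one row per nucleus per frame) with columns
#'   nucleus_id, frame, t_seconds, ap_um, dv_um, el_pct, fluor_ms2,
#'   fluor_pp7, true_state; the geometry, genotype and seed are attached
#'   as attributes.  Bit-identical for a fixed seed.
#' @export
simulate_traces <- function(embryo) {
  stopifnot(inherits(embryo, "embryo_sim"))
  nuc <- embryo$nuclei
  if (nrow(nuc) == 0) stop("embryo has no nuclei")
  g <- embryo$geometry
  frames <- seq(0, floor(g$nc14_duration / g$frame_interval))
  t_sec <- frames * g$frame_interval
  t_norm <- t_sec / g$nc14_duration
  n <- nrow(nuc)
  nf <- length(frames)
  het <- embryo$genotype == "kr_het"

  with_seed(embryo$seed, {
    jit <- if (embryo$stripe_jitter_el > 0)
      stats::runif(length(embryo$rules), -embryo$stripe_jitter_el,
                   embryo$stripe_jitter_el)
    else rep(0, length(embryo$rules))

    # per-frame per-nucleus rate and amplitude fields
    kon <- matrix(0, n, nf)
    koff <- matrix(0.02, n, nf)
    amp <- matrix(0, n, nf)
    for (si in seq_along(embryo$rules)) {
      r <- embryo$rules[[si]]
      d <- r$genotype_deltas
      onset <- r$onset_time + if (het) d$onset_delay_s / g$nc14_duration else 0
      r_amp <- r$loading_amplitude * if (het) d$amplitude_factor else 1
      r_kon <- r$k_on_max * if (het) d$k_on_factor else 1
      for (f in seq_len(nf)) {
        if (t_norm[f] < onset) next
        e <- stripe_edges(r, t_norm[f], embryo$genotype, g$el_per_nucleus,
                          jitter_el = jit[si])
        member <- nuc$el_pct >= e[1] & nuc$el_pct <= e[2]
        if (!any(member)) next
        k <- if (embryo$engine == "regulators") {
          conc <- vapply(names(embryo$regulators), function(gn)
            mean(gap_profile(gn, nuc$el_pct[member], t_norm[f],
                             embryo$genotype, embryo$regulators)),
            numeric(1))
          stripe_rate(r, conc, t_norm[f])$k_on
        } else r_kon
        kon[member, f] <- k
        koff[member, f] <- r$k_off
        amp[member, f] <- r_amp
      }
    }

    # exact frame-time sampling of the telegraph state
    state <- matrix(FALSE, n, nf)
    if (embryo$bursting) {
      dt <- g$frame_interval
      s <- rep(FALSE, n)
      for (f in 2:nf) {
        r_tot <- kon[, f] + koff[, f]
        p_inf <- ifelse(r_tot > 0, kon[, f] / r_tot, 0)
        relax <- exp(-r_tot * dt)
        p_on <- p_inf + (as.numeric(s) - p_inf) * relax
        s <- stats::runif(n) < p_on
        state[, f] <- s
      }
    } else {
      state <- kon > 0
    }

    fl_ms2 <- embryo$baseline + amp * state
    if (embryo$noise_sd > 0)
      fl_ms2 <- fl_ms2 + matrix(stats::rnorm(n * nf, 0, embryo$noise_sd), n, nf)
    fl_ms2 <- pmax(fl_ms2, 0)

    fl_pp7 <- matrix(0, n, nf)
    if (embryo$has_pp7_reporter) {
      in_dom <- nuc$el_pct >= embryo$pp7_domain[1] &
        nuc$el_pct <= embryo$pp7_domain[2]
      on_t <- t_norm >= embryo$pp7_onset
      fl_pp7[in_dom, on_t] <- embryo$pp7_amplitude
    }
    if (embryo$noise_sd > 0)
      fl_pp7 <- fl_pp7 + matrix(stats::rnorm(n * nf, 0, embryo$noise_sd), n, nf)
    fl_pp7 <- pmax(fl_pp7, 0)

    out <- data.frame(
      nucleus_id = rep(nuc$nucleus_id, each = nf),
      frame = rep(frames, n),
      t_seconds = rep(t_sec, n),
      ap_um = rep(nuc$ap_um, each = nf),
      dv_um = rep(nuc$dv_um, each = nf),
      el_pct = rep(nuc$el_pct, each = nf),
      fluor_ms2 = as.vector(t(fl_ms2)),
      fluor_pp7 = as.vector(t(fl_pp7)),
      true_state = as.integer(t(state)))
    attr(out, "geometry") <- g
    attr(out, "genotype") <- embryo$genotype
    attr(out, "seed") <- embryo$seed
    out
  })
}

#' Simulate a cohort of embryos
#'
#' @param n number of embryos
#' @param genotype "wt" or "kr_het"
#' @param seed base seed; embryo i uses seed + i - 1
#' @param ... passed to \code{\link{embryo_sim}}
#' @return list of trace tables (see \code{\link{simulate_traces}})
#' @export
simulate_cohort <- function(n, genotype = "wt", seed = 1, ...) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i)
    simulate_traces(embryo_sim(genotype = genotype, seed = seed + i - 1, ...)))
}
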