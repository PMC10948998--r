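#' Embryo geometry for synthetic blastoderm monolayers
#'
#' Defines the nucleus lattice and time base of a synthetic embryo.  The
#' defaults emulate the imaging conditions this pipeline targets: a fixed
#' 282 um dorsoventral (DV) analysis window spanning ~17 nuclei in the
#' middle of the embryo, and a 61 s frame interval over nuclear cycle 14
#' (NC14, ~51 min).  Along the anterior-posterior (AP) axis the default
#' lattice has 100 nucleus columns over a 500 um embryo, so one nucleus
#' column corresponds to exactly 1% egg length (%EL); this makes planted
#' effect sizes stated in "nuclei" exact on the grid.
#'
#' @param ap_length embryo AP length, um
#' @param dv_window height of the DV analysis window, um
#' @param n_ap_nuclei number of nucleus columns along AP
#' @param n_dv_nuclei number of nucleus rows across the DV window
#' @param frame_interval imaging frame interval, seconds
#' @param nc14_duration duration of NC14 (end of 13th mitosis to
#'   gastrulation), seconds
#'
#' @return an object of class \code{embryo_geometry}: a list with the
#'   arguments plus derived spacings \code{ap_spacing} (um),
#'   \code{dv_spacing} (um) and \code{el_per_nucleus} (%EL per nucleus
#'   column, the conversion factor between %EL and "nuclei" units).
#' @export
#' @examples
#' g <- embryo_geometry()
#' g$el_per_nucleus  # 1 nucleus column = 1 %EL by default
embryo_geometry <- function(ap_length = 500, dv_window = 282,
                            n_ap_nuclei = 100, n_dv_nuclei = 17,
                            frame_interval = 61, nc14_duration = 3050) {
  stopifnot(ap_length > 0, dv_window > 0, n_ap_nuclei >= 1,
            n_dv_nuclei >= 1, frame_interval > 0, nc14_duration > 0)
  g <- list(ap_length = ap_length, dv_window = dv_window,
            n_ap_nuclei = as.integer(n_ap_nuclei),
            n_dv_nuclei = as.integer(n_dv_nuclei),
            frame_interval = frame_interval,
            nc14_duration = nc14_duration)
  g$ap_spacing <- ap_length / n_ap_nuclei
  g$dv_spacing <- dv_window / n_dv_nuclei
  g$el_per_nucleus <- 100 / n_ap_nuclei
  structure(g, class = "embryo_geometry")
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf(
    "Embryo geometry: %g um AP x %g um DV window; %d x %d nuclei (%.2f / %.2f um spacing)\n",
    x$ap_length, x$dv_window, x$n_ap_nuclei, x$n_dv_nuclei,
    x$ap_spacing, x$dv_spacing))
  cat(sprintf("  %g s/frame over %g s of NC14 (1 nucleus = %.3g %%EL)\n",
              x$frame_interval, x$nc14_duration, x$el_per_nucleus))
  invisible(x)
}

#' Nucleus lattice of a geometry
#'
#' Nucleus centers sit mid-cell: column j at (j - 1/2) * ap_spacing along
#' AP, row i at (i - 1/2) * dv_spacing, with DV coordinates centered on
#' the embryo midline (dv = 0).
#'
#' @param geometry an \code{\link{embryo_geometry}}
#' @return data.frame with nucleus_id, ap_um, dv_um, el_pct
#' @export
nucleus_lattice <- function(geometry) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  ap <- (seq_len(geometry$n_ap_nuclei) - 0.5) * geometry$ap_spacing
  dv <- (seq_len(geometry$n_dv_nuclei) - 0.5) * geometry$dv_spacing -
    geometry$dv_window / 2
  grid <- expand.grid(ap_um = ap, dv_um = dv, KEEP.OUT.ATTRS = FALSE)
  data.frame(nucleus_id = seq_len(nrow(grid)),
             ap_um = grid$ap_um, dv_um = grid$dv_um,
             el_pct = 100 * grid$ap_um / geometry$ap_length)
}

#' Gap-gene-like regulator profile
#'
#' A smooth AP expression bump built from a product of two logistic edges,
#' normalized so its value at \code{center} equals \code{amplitude} times
#' the temporal ramp.  Concentration units are arbitrary (a.u.); only
#' relative levels matter to the stripe rules.  Genotype presets modify the
#' profile multiplicatively (\code{genotype_scaling}, e.g. 0.5 for Kr under
#' halved dosage) and/or by an AP displacement (\code{genotype_shift}, %EL,
#' negative = anterior).
#'
#' @param gene regulator name
#' @param amplitude peak concentration, a.u.
#' @param center bump center, %EL (anterior tip = 0)
#' @param half_width half-width of the bump plateau, %EL
#' @param edge_steepness logistic steepness, 1/%EL
#' @param temporal_ramp function of normalized time t in [0,1] returning a
#'   dimensionless multiplier
#' @param genotype_scaling multiplier applied in the Kr-heterozygote preset
#' @param genotype_shift domain displacement in the heterozygote, %EL
#' @return a \code{regulator_profile} object (list)
#' @export
regulator_profile <- function(gene, amplitude = 1, center = 50,
                              half_width = 10, edge_steepness = 1,
                              temporal_ramp = function(t) pmin(1, t / 0.3),
                              genotype_scaling = 1, genotype_shift = 0) {
  stopifnot(amplitude >= 0, half_width > 0, center >= 0, center <= 100,
            edge_steepness > 0, is.function(temporal_ramp))
  structure(list(gene = gene, amplitude = amplitude, center = center,
                 half_width = half_width, edge_steepness = edge_steepness,
                 temporal_ramp = temporal_ramp,
                 genotype_scaling = genotype_scaling,
                 genotype_shift = genotype_shift),
            class = "regulator_profile")
}

#' Default regulator set
#'
#' Six gap-gene-like fields (Kr; anterior/posterior gt; kni;
#' anterior/posterior hb) with heterozygote modifications encoding the
#' regulatory logic of halved Kr dosage: Kr itself is halved everywhere;
#' the posterior gt stripe and the kni domain sit more anteriorly; the
#' anterior hb domain is reduced in level.  Centers and widths are in %EL;
#' amplitudes are arbitrary units.
#'
#' @return named list of \code{\link{regulator_profile}} objects
#' @export
default_regulators <- function() {
  list(
    Kr      = regulator_profile("Kr",      amplitude = 1.0, center = 50,
                                half_width = 12, genotype_scaling = 0.5),
    gt_ant  = regulator_profile("gt_ant",  amplitude = 1.0, center = 20,
                                half_width = 8),
    gt_post = regulator_profile("gt_post", amplitude = 1.0, center = 80,
                                half_width = 6, genotype_shift = -3),
    kni     = regulator_profile("kni",     amplitude = 1.0, center = 65,
                                half_width = 8, genotype_shift = -2),
    hb_ant  = regulator_profile("hb_ant",  amplitude = 1.0, center = 22,
                                half_width = 22, genotype_scaling = 0.85),
    hb_post = regulator_profile("hb_post", amplitude = 1.0, center = 88,
                                half_width = 7)
  )
}

#' Evaluate a regulator concentration field
#'
#' @param gene regulator name (must be present in \code{regulators})
#' @param x AP position(s), %EL in [0, 100]
#' @param t normalized time in [0, 1] (scalar or same length as x)
#' @param genotype "wt" or "kr_het"
#' @param regulators named list of \code{\link{regulator_profile}}s
#' @return concentration(s), a.u.; for gene = "Kr" the kr_het value is
#'   exactly half the wt value at every (x, t)
#' @export
#' @examples
#' gap_profile("Kr", 50, 0.5)                       # bump maximum
#' gap_profile("Kr", 40, 0.5, genotype = "kr_het")  # halved dosage
gap_profile <- function(gene, x, t, genotype = c("wt", "kr_het"),
                        regulators = default_regulators()) {
  genotype <- match.arg(genotype)
  if (!gene %in% names(regulators))
    stop("unknown gene '", gene, "'; valid genes: ",
         paste(names(regulators), collapse = ", "))
  stopifnot(all(x >= 0 & x <= 100), all(t >= 0 & t <= 1))
  p <- regulators[[gene]]
  het <- genotype == "kr_het"
  ctr <- p$center + if (het) p$genotype_shift else 0
  s <- p$edge_steepness
  w <- p$half_width
  bump <- function(z) stats::plogis(s * (z - (ctr - w))) *
    stats::plogis(-s * (z - (ctr + w)))
  val <- p$amplitude * p$temporal_ramp(t) * bump(x) / bump(ctr)
  if (het) val <- val * p$genotype_scaling
  val
}
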