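#' Stripe rule: transcription parameters and planted genotype effects
#'
#' Each of the seven stripes carries a telegraph-model parameter set (burst
#' on-rate, off-rate, loading amplitude), an activation onset in normalized
#' NC14 time, its wild-type mature extent in %EL, and the repression logic
#' linking burst propensity to regulator concentrations.  The
#' \code{genotype_deltas} plant the Kr-heterozygote effects directly, giving
#' an unambiguous ground truth for recovery tests:
#' \itemize{
#'   \item \code{width_delta_nuclei}: mature width change (negative =
#'     narrower), split symmetrically across both edges
#'   \item \code{position_shift_nuclei}: rigid AP shift (negative =
#'     toward the anterior tip)
#'   \item \code{onset_delay_s}: activation onset delay, seconds
#'   \item \code{amplitude_factor}: multiplier on the loading amplitude
#'   \item \code{k_on_factor}: multiplier on the burst on-rate (sporadic
#'     activity when < 1)
#'   \item \code{transient_expansion_nuclei}: peak transient extension of
#'     the posterior edge around mid-NC14 (triangular time course peaking
#'     at \code{expansion_peak_t}, support +/- \code{expansion_half_t})
#' }
#'
#' @param stripe_id integer 1..7
#' @param anterior,posterior wild-type mature stripe edges, %EL
#' @param loading_amplitude fluorescence emitted while the promoter is ON,
#'   a.u.
#' @param k_on_max,k_off telegraph switching rates, 1/s
#' @param onset_time activation onset, normalized NC14 time in [0,1]
#' @param activator_floor repression capacity: summed weighted repressor
#'   concentration at which the on-rate reaches zero, a.u.
#' @param repressor_weights named numeric of per-regulator weights
#' @param genotype_deltas list of planted heterozygote modifications (see
#'   Details); missing entries default to neutral values
#' @param expansion_peak_t,expansion_half_t time course of the transient
#'   posterior expansion (normalized time)
#' @return a \code{stripe_rule} object (list)
#' @export
stripe_rule <- function(stripe_id, anterior, posterior,
                        loading_amplitude = 100,
                        k_on_max = 0.1, k_off = 0.02,
                        onset_time = 0.1,
                        activator_floor = 1,
                        repressor_weights = numeric(0),
                        genotype_deltas = list(),
                        expansion_peak_t = 0.55, expansion_half_t = 0.2) {
  stopifnot(stripe_id >= 1, stripe_id <= 7, anterior < posterior,
            k_on_max >= 0, k_off >= 0, onset_time >= 0, onset_time <= 1,
            loading_amplitude >= 0, activator_floor > 0)
  d <- utils::modifyList(
    list(width_delta_nuclei = 0, position_shift_nuclei = 0,
         onset_delay_s = 0, amplitude_factor = 1, k_on_factor = 1,
         transient_expansion_nuclei = 0),
    genotype_deltas)
  structure(list(stripe_id = as.integer(stripe_id),
                 anterior = anterior, posterior = posterior,
                 loading_amplitude = loading_amplitude,
                 k_on_max = k_on_max, k_off = k_off,
                 onset_time = onset_time,
                 activator_floor = activator_floor,
                 repressor_weights = repressor_weights,
                 genotype_deltas = d,
                 expansion_peak_t = expansion_peak_t,
                 expansion_half_t = expansion_half_t),
            class = "stripe_rule")
}

#' Default stripe rules (wild type + planted heterozygote effects)
#'
#' Seven stripes, 4 %EL wide, centers 8 %EL apart between 28 and 84 %EL,
#' activating sequentially in early NC14.  The planted Kr-heterozygote
#' effects mirror the reported phenotypes: a transient ~1.6-nuclei
#' posterior expansion of stripe 2 around mid-NC14; stripes 3 and 4
#' ~0.9 nuclei narrower with reduced loading amplitude; an anterior shift
#' of the whole stripe-4 domain, a ~6-min stripe-4 onset delay and
#' sporadic stripe-4 bursting; and a ~3-nuclei anterior shift of stripe 5.
#' Stripe 3 narrows from its posterior edge only (position shift = half
#' the width change).
#'
#' @return named list of \code{\link{stripe_rule}} objects ("s1".."s7")
#' @export
default_stripe_rules <- function() {
  list(
    s1 = stripe_rule(1, 28, 32, onset_time = 0.10,
                     repressor_weights = c(gt_ant = 1, hb_ant = 0.3)),
    s2 = stripe_rule(2, 38, 42, onset_time = 0.08,
                     repressor_weights = c(gt_ant = 1, Kr = 1),
                     genotype_deltas = list(transient_expansion_nuclei = 1.6)),
    s3 = stripe_rule(3, 48, 52, onset_time = 0.12,
                     repressor_weights = c(hb_ant = 1, kni = 1),
                     genotype_deltas = list(width_delta_nuclei = -0.9,
                                            position_shift_nuclei = -0.45,
                                            amplitude_factor = 0.75)),
    s4 = stripe_rule(4, 56, 60, onset_time = 0.25,
                     repressor_weights = c(hb_ant = 1, kni = 1),
                     genotype_deltas = list(width_delta_nuclei = -0.9,
                                            position_shift_nuclei = -1,
                                            onset_delay_s = 360,
                                            amplitude_factor = 0.7,
                                            k_on_factor = 0.75)),
    s5 = stripe_rule(5, 64, 68, onset_time = 0.15,
                     repressor_weights = c(Kr = 1, gt_post = 1),
                     genotype_deltas = list(position_shift_nuclei = -3)),
    s6 = stripe_rule(6, 72, 76, onset_time = 0.18,
                     repressor_weights = c(kni = 1)),
    s7 = stripe_rule(7, 80, 84, onset_time = 0.20,
                     repressor_weights = c(gt_post = 1))
  )
}

#' Burst propensity from regulator concentrations
#'
#' Maps the repression logic to a telegraph on-rate: before the stripe's
#' onset time the on-rate is zero; afterwards
#' \code{k_on = k_on_max * max(0, 1 - sum(w_i c_i) / activator_floor)},
#' clipped to [0, k_on_max].  Monotone non-increasing in every repressor
#' concentration.
#'
#' @param rule a \code{\link{stripe_rule}}
#' @param concentrations named numeric of regulator concentrations (a.u.,
#'   all >= 0); regulators without a weight are ignored
#' @param t normalized time in [0,1]
#' @return list with \code{k_on} (1/s) and \code{loading_amplitude} (a.u.)
#' @export
stripe_rate <- function(rule, concentrations, t) {
  stopifnot(inherits(rule, "stripe_rule"))
  if (any(concentrations < 0)) stop("negative regulator concentration")
  if (t < rule$onset_time)
    return(list(k_on = 0, loading_amplitude = rule$loading_amplitude))
  w <- rule$repressor_weights
  load <- if (length(w)) {
    cc <- concentrations[names(w)]
    cc[is.na(cc)] <- 0
    sum(w * cc)
  } else 0
  k_on <- rule$k_on_max * max(0, 1 - load / rule$activator_floor)
  list(k_on = min(max(k_on, 0), rule$k_on_max),
       loading_amplitude = rule$loading_amplitude)
}

# effective stripe edges at one normalized time for one genotype, in %EL.
# jitter_el: per-embryo rigid displacement of this stripe (embryo-to-embryo
# variability).  Returns c(anterior, posterior).
stripe_edges <- function(rule, t, genotype, el_per_nucleus, jitter_el = 0) {
  ant <- rule$anterior + jitter_el
  post <- rule$posterior + jitter_el
  if (genotype == "kr_het") {
    d <- rule$genotype_deltas
    shift <- d$position_shift_nuclei * el_per_nucleus
    half_wd <- d$width_delta_nuclei * el_per_nucleus / 2
    ant <- ant + shift - half_wd
    post <- post + shift + half_wd
    if (d$transient_expansion_nuclei != 0) {
      bump <- pmax(0, 1 - abs(t - rule$expansion_peak_t) / rule$expansion_half_t)
      post <- post + d$transient_expansion_nuclei * el_per_nucleus * bump
    }
  }
  c(ant, post)
}
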