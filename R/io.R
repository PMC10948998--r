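trace_columns <- c("nucleus_id", "frame", "t_seconds", "ap_um", "dv_um",
                   "el_pct", "fluor_ms2", "fluor_pp7", "true_state")

#' Read and write trace tables
#'
#' Trace tables are plain CSV with the columns nucleus_id, frame,
#' t_seconds, ap_um, dv_um, el_pct, fluor_ms2, fluor_pp7, true_state
#' (the last two optional on read).  Reading validates the header and
#' that frames are strictly increasing within each nucleus.
#'
#' @param path CSV file path
#' @param table a trace table data.frame
#' @return \code{read_traces}: the validated trace table;
#'   \code{write_traces}: the path, invisibly
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path)
  required <- setdiff(trace_columns, c("fluor_pp7", "true_state"))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column ", paste(missing, collapse = ", "))
  bad <- tapply(tab$frame, tab$nucleus_id, function(f) is.unsorted(f, strictly = TRUE))
  if (any(bad))
    stop("non-monotone frames for nucleus ",
         paste(names(bad)[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  tab
}

#' @rdname read_traces
#' @export
write_traces <- function(table, path) {
  keep <- intersect(trace_columns, names(table))
  utils::write.csv(table[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A serializable bundle of every tunable the pipeline uses.  Round-trips
#' through YAML unchanged (\code{\link{write_config}} /
#' \code{\link{read_config}}).
#'
#' @param seed base random seed
#' @param n_wt,n_het cohort sizes
#' @param geometry named list of \code{\link{embryo_geometry}} arguments
#' @param noise_sd,baseline,stripe_jitter_el simulator settings
#' @param threshold active-call threshold ("auto" or numeric)
#' @param dv_window_um DV analysis window, um
#' @param n_time_points,n_bins,n_sections grid sizes
#' @param summary_window,expansion_window analysis windows (normalized
#'   time)
#' @param onset_frac kinetics onset fraction
#' @param neutral_het if TRUE the heterozygote preset has all genotype
#'   deltas removed (null cohorts)
#' @param log_level "info" or "quiet"
#' @return a \code{run_config} list
#' @export
run_config <- function(seed = 1, n_wt = 10, n_het = 10,
                       geometry = list(), noise_sd = 5, baseline = 10,
                       stripe_jitter_el = 0.5, threshold = "auto",
                       dv_window_um = 282, n_time_points = 100,
                       n_bins = 50, n_sections = 5,
                       summary_window = c(0.80, 0.90),
                       expansion_window = c(0.40, 0.70),
                       onset_frac = 0.10, neutral_het = FALSE,
                       log_level = "info") {
  structure(list(seed = as.integer(seed), n_wt = n_wt, n_het = n_het,
                 geometry = geometry, noise_sd = noise_sd,
                 baseline = baseline, stripe_jitter_el = stripe_jitter_el,
                 threshold = threshold, dv_window_um = dv_window_um,
                 n_time_points = n_time_points, n_bins = n_bins,
                 n_sections = n_sections, summary_window = summary_window,
                 expansion_window = expansion_window,
                 onset_frac = onset_frac, neutral_het = neutral_het,
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}
#' @param path YAML file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Neutralized stripe rules (null heterozygote preset)
#'
#' Default stripe rules with every planted genotype delta set to its
#' neutral value, so wild-type and heterozygote cohorts are statistically
#' indistinguishable.
#'
#' @return named list of \code{\link{stripe_rule}}s
#' @export
neutral_stripe_rules <- function() {
  lapply(default_stripe_rules(), function(r) {
    r$genotype_deltas <- list(width_delta_nuclei = 0,
                              position_shift_nuclei = 0, onset_delay_s = 0,
                              amplitude_factor = 1, k_on_factor = 1,
                              transient_expansion_nuclei = 0)
    r
  })
}

#' Run the full synthetic pipeline
#'
#' Simulates wild-type and Kr-heterozygote cohorts, analyzes every
#' embryo, compares the genotypes and writes all artifacts (trace CSVs,
#' boundary-track and kinetics CSVs, CV profiles, a machine-readable
#' summary JSON, and a log recording every threshold and window used) to
#' an output directory.  Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{run_config}}
#' @param out_dir output directory (created if needed); NULL analyzes
#'   without writing files
#' @return (invisibly) list with wt/het record lists, the
#'   \code{\link{compare_genotypes}} report, cv profiles and the summary
#'   list
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (identical(config$log_level, "info")) message(msg)
  }
  geom <- do.call(embryo_geometry, config$geometry)
  rules <- if (isTRUE(config$neutral_het)) neutral_stripe_rules()
  else default_stripe_rules()
  say("pipeline: %d wt + %d het embryos, seed %d, threshold %s",
      config$n_wt, config$n_het, config$seed, as.character(config$threshold))
  say("windows: summary [%.2f, %.2f], expansion [%.2f, %.2f], DV %g um",
      config$summary_window[1], config$summary_window[2],
      config$expansion_window[1], config$expansion_window[2],
      config$dv_window_um)

  sim_one <- function(genotype, seed)
    simulate_traces(embryo_sim(genotype = genotype, geometry = geom,
                               rules = rules, seed = seed,
                               noise_sd = config$noise_sd,
                               baseline = config$baseline,
                               stripe_jitter_el = config$stripe_jitter_el))
  analyze_one <- function(traces, tag) {
    rec <- analyze_embryo(traces, dv_window_um = config$dv_window_um,
                          threshold = config$threshold,
                          n_time_points = config$n_time_points,
                          n_bins = config$n_bins,
                          n_sections = config$n_sections)
    say("%s: classified %s, %d stripes, active-call threshold %.3f a.u.",
        tag, rec$genotype, nrow(rec$domains), rec$threshold)
    rec
  }
  wt_traces <- lapply(seq_len(config$n_wt), function(i)
    sim_one("wt", config$seed + i - 1))
  het_traces <- lapply(seq_len(config$n_het), function(i)
    sim_one("kr_het", config$seed + 1000 + i - 1))
  wt <- lapply(seq_along(wt_traces), function(i)
    analyze_one(wt_traces[[i]], paste0("wt_", i)))
  het <- lapply(seq_along(het_traces), function(i)
    analyze_one(het_traces[[i]], paste0("het_", i)))

  report <- compare_genotypes(wt, het, summary_window = config$summary_window,
                              expansion_window = config$expansion_window,
                              onset_frac = config$onset_frac)
  cv_wt <- cv_profile(lapply(wt, `[[`, "profile"))
  cv_het <- cv_profile(lapply(het, `[[`, "profile"))

  summary <- list(
    n_wt = length(wt), n_het = length(het),
    n_stripes = vapply(c(wt, het), function(r) nrow(r$domains), integer(1)),
    thresholds = vapply(c(wt, het), `[[`, numeric(1), "threshold"),
    stripe2_expansion_nuclei = report$stripe2_expansion_nuclei,
    stripes = report$stripes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(wt_traces))
      write_traces(wt_traces[[i]], file.path(out_dir,
                                             sprintf("traces_wt_%02d.csv", i)))
    for (i in seq_along(het_traces))
      write_traces(het_traces[[i]], file.path(out_dir,
                                              sprintf("traces_het_%02d.csv", i)))
    utils::write.csv(do.call(rbind, lapply(seq_along(wt), function(i)
      cbind(embryo = i, genotype = "wt", wt[[i]]$bt))),
      file.path(out_dir, "boundary_tracks_wt.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(seq_along(het), function(i)
      cbind(embryo = i, genotype = "kr_het", het[[i]]$bt))),
      file.path(out_dir, "boundary_tracks_het.csv"), row.names = FALSE)
    utils::write.csv(cv_wt, file.path(out_dir, "cv_profile_wt.csv"),
                     row.names = FALSE)
    utils::write.csv(cv_het, file.path(out_dir, "cv_profile_het.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(list(wt = wt, het = het, report = report,
                 cv_wt = cv_wt, cv_het = cv_het, summary = summary))
}
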