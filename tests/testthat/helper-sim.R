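# Shared small fixtures, built in code.

# compact lattice for fast simulations (15 columns, 4 rows, 31 frames)
mini_geometry <- function(n_frames = 30)
  embryo_geometry(ap_length = 150, dv_window = 66, n_ap_nuclei = 15,
                  n_dv_nuclei = 4, frame_interval = 61,
                  nc14_duration = 61 * n_frames)

# single stripe occupying columns at 30-60 %EL of the mini geometry
mini_rules <- function(...)
  list(s1 = stripe_rule(1, 30, 60, onset_time = 0.1, ...))

mini_embryo <- function(genotype = "wt", seed = 1, ...)
  embryo_sim(genotype, geometry = mini_geometry(), rules = mini_rules(),
             seed = seed, ...)

# hand-built normalized_traces object
make_nt <- function(el, dv, active, fluor = NULL, t_norm = NULL,
                    threshold = 0) {
  n_t <- ncol(active)
  if (is.null(t_norm)) t_norm <- seq(0, 1, length.out = n_t)
  if (is.null(fluor)) fluor <- ifelse(active, 1, 0)
  structure(list(nucleus_id = seq_along(el), el_pct = el, dv_um = dv,
                 t_norm = t_norm, fluor = fluor, active = active,
                 threshold = threshold, background = NULL,
                 geometry = NULL, genotype = NULL),
            class = "normalized_traces")
}

# label-mask stub from centroids only (for tracking tests)
make_mask <- function(x, y) {
  structure(list(labels = NULL,
                 centroids = data.frame(label = seq_along(x), x_px = x,
                                        y_px = y,
                                        area = rep(1L, length(x)))),
            class = "label_mask")
}

# sparse geometry suitable for rendering (16.6 um spacing at 1 px/um)
render_geometry <- function(n_ap = 10, n_dv = 5, n_frames = 3)
  embryo_geometry(ap_length = n_ap * 16.6, dv_window = n_dv * 16.6,
                  n_ap_nuclei = n_ap, n_dv_nuclei = n_dv,
                  frame_interval = 61, nc14_duration = 61 * n_frames)
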