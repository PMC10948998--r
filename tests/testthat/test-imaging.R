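test_that("max projection collapses z and passes 2D through", {
  z <- array(0, c(4, 5, 3))
  z[2, 3, 2] <- 7
  expect_equal(max_project(z)[2, 3], 7)
  m <- matrix(1:6, 2, 3)
  expect_identical(max_project(m), m)
})

test_that("rendering honors its geometric contract", {
  g <- render_geometry(n_ap = 4, n_dv = 2, n_frames = 2)
  emb <- embryo_sim("wt", geometry = g, rules = list(
    s1 = stripe_rule(1, 0, 100, onset_time = 0)), seed = 1,
    noise_sd = 0, baseline = 0, bursting = FALSE, stripe_jitter_el = 0)
  tr <- simulate_traces(emb)
  expect_error(render_frames(emb, tr, nucleus_radius_px = 10),
               "overlap")
  # zero nuclei: both channels flat at background
  emb0 <- emb
  emb0$nuclei <- emb0$nuclei[0, ]
  tr0 <- tr[0, ]
  st0 <- render_frames(emb0, tr0, nucleus_radius_px = 5, background = 3)
  expect_true(all(st0$frames[[1]]$nuclei == 3))
  expect_true(all(st0$frames[[1]]$ms2 == 3))
  # determinism under a fixed seed (with pixel noise on)
  s1 <- render_frames(emb, tr, noise_sd = 2, seed = 99)
  s2 <- render_frames(emb, tr, noise_sd = 2, seed = 99)
  expect_identical(s1, s2)
})

test_that("the top-2-pixel readout recovers a rendered punctum peak", {
  g <- embryo_geometry(ap_length = 30, dv_window = 30, n_ap_nuclei = 1,
                       n_dv_nuclei = 1, frame_interval = 61,
                       nc14_duration = 61)
  emb <- embryo_sim("wt", geometry = g, rules = list(
    s1 = stripe_rule(1, 0, 100, onset_time = 0, loading_amplitude = 87)),
    seed = 1, noise_sd = 0, baseline = 0, bursting = FALSE,
    stripe_jitter_el = 0)
  tr <- simulate_traces(emb)
  on <- tr[tr$true_state == 1, ][1, ]
  st <- render_frames(emb, tr, nucleus_radius_px = 5, psf_sigma_px = 3)
  fi <- which(sort(unique(tr$frame)) == on$frame)
  mask <- segment_nuclei(st$frames[[fi]]$nuclei)
  expect_equal(nrow(mask$centroids), 1)
  sig <- measure_ms2(st$frames[[fi]]$ms2, mask)
  expect_lt(abs(sig - 87) / 87, 0.05)
})

test_that("segmentation finds every planted nucleus within a pixel", {
  g <- render_geometry(n_ap = 10, n_dv = 5, n_frames = 1)
  emb <- embryo_sim("wt", geometry = g, rules = mini_rules(), seed = 4,
                    noise_sd = 0, baseline = 0)
  tr <- simulate_traces(emb)
  st <- render_frames(emb, tr, nucleus_radius_px = 5)
  mask <- segment_nuclei(st$frames[[1]]$nuclei)
  expect_equal(nrow(mask$centroids), 50)
  planted_x <- emb$nuclei$ap_um * st$meta$px_per_um + st$meta$margin_px
  planted_y <- (emb$nuclei$dv_um + g$dv_window / 2) * st$meta$px_per_um +
    st$meta$margin_px
  for (i in seq_len(50)) {
    d <- sqrt((mask$centroids$x_px - planted_x[i])^2 +
              (mask$centroids$y_px - planted_y[i])^2)
    expect_lt(min(d), 1)
  }
  # blank image: zero labels, not an error
  blank <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(blank$centroids), 0)
})

test_that("blobs merged below the blur scale yield one label", {
  img <- matrix(0, 40, 40)
  for (cx in c(18, 23)) {  # two discs 5 px apart, radius 4: they touch
    for (i in 1:40) for (j in 1:40)
      if ((i - 20)^2 + (j - cx)^2 <= 16) img[i, j] <- 100
  }
  mask <- segment_nuclei(img, blur_sigma = 2, min_area_px = 10)
  expect_equal(nrow(mask$centroids), 1)
})

test_that("tracking links static and jittered nuclei, splits on jumps", {
  # static: n tracks, each of length 10
  xs <- c(10, 30, 50); ys <- c(20, 20, 20)
  masks <- replicate(10, make_mask(xs, ys), simplify = FALSE)
  tk <- track_nuclei(masks, max_step_px = 5)
  expect_equal(length(unique(tk$nucleus_id)), 3)
  expect_true(all(table(tk$nucleus_id) == 10))
  # a jump beyond max_step starts a new track
  masks2 <- list(make_mask(10, 10), make_mask(30, 10))
  tk2 <- track_nuclei(masks2, max_step_px = 5)
  expect_equal(length(unique(tk2$nucleus_id)), 2)
  # jittered movie: identity preserved vs planted positions
  set.seed(101)
  base_x <- rep(seq(10, 90, by = 16), each = 3)
  base_y <- rep(c(15, 40, 65), times = 6)
  masks3 <- lapply(1:12, function(f)
    make_mask(base_x + rnorm(length(base_x), 0, 0.5),
              base_y + rnorm(length(base_y), 0, 0.5)))
  tk3 <- track_nuclei(masks3, max_step_px = 5)
  expect_equal(length(unique(tk3$nucleus_id)), length(base_x))
  first <- tk3[tk3$frame == 1, ]
  planted_id <- vapply(seq_len(nrow(first)), function(i)
    which.min((base_x - first$x_px[i])^2 + (base_y - first$y_px[i])^2),
    integer(1))
  for (f in 2:12) {
    cur <- tk3[tk3$frame == f, ]
    cur_planted <- vapply(seq_len(nrow(cur)), function(i)
      which.min((base_x - cur$x_px[i])^2 + (base_y - cur$y_px[i])^2),
      integer(1))
    # the persistent id must map to the same planted nucleus every frame
    m1 <- planted_id[match(cur$nucleus_id, first$nucleus_id)]
    expect_equal(m1, cur_planted)
  }
})

test_that("measure_ms2 averages the two brightest pixels per label", {
  frame <- matrix(c(1, 2, 3, 9), 2, 2)
  labels <- matrix(c(1L, 1L, 1L, 0L), 2, 2)
  expect_equal(unname(measure_ms2(frame, labels)), 2.5)  # {1,2,3} -> 2.5
  # uniform nucleus and single-pixel label
  frame2 <- matrix(5, 3, 3)
  labels2 <- matrix(0L, 3, 3)
  labels2[1:2, 1] <- 1L
  labels2[3, 3] <- 2L
  expect_equal(unname(measure_ms2(frame2, labels2)), c(5, 5))
  # corrupt mask: a declared label without pixels
  mask <- structure(list(labels = labels2,
                         centroids = data.frame(label = c(1L, 2L, 3L),
                                                x_px = 0, y_px = 0,
                                                area = 1L)),
                    class = "label_mask")
  expect_error(measure_ms2(frame2, mask), "corrupt mask")
})

test_that("measure_ms2 matches brute force, permutation and monotonicity", {
  set.seed(107)
  for (trial in 1:20) {
    h <- 30; w <- 30
    labels <- matrix(0L, h, w)
    n_lab <- sample(3:8, 1)
    for (l in seq_len(n_lab)) {
      px <- sample(h * w, sample(1:12, 1))
      labels[px] <- l  # later labels may overwrite: some may vanish
    }
    present <- sort(unique(labels[labels > 0]))
    frame <- matrix(runif(h * w, 0, 100), h, w)
    sig <- measure_ms2(frame, labels)
    for (l in present)
      expect_equal(unname(sig[as.character(l)]),
                   oracle_top2(frame[labels == l]))
  }
  # permutation invariance within a label; monotone in any pixel
  labels <- matrix(0L, 4, 4)
  labels[1, 1:4] <- 1L
  f1 <- matrix(0, 4, 4); f1[1, ] <- c(4, 1, 3, 2)
  f2 <- matrix(0, 4, 4); f2[1, ] <- c(1, 2, 3, 4)
  expect_equal(measure_ms2(f1, labels), measure_ms2(f2, labels))
  f3 <- f1; f3[1, 2] <- 50
  expect_gte(unname(measure_ms2(f3, labels)),
             unname(measure_ms2(f1, labels)))
})

test_that("the image path recovers planted trace amplitudes end to end", {
  g <- render_geometry(n_ap = 8, n_dv = 3, n_frames = 6)
  emb <- embryo_sim("wt", geometry = g,
                    rules = list(s1 = stripe_rule(1, 20, 80, onset_time = 0.2,
                                                  loading_amplitude = 120)),
                    seed = 6, noise_sd = 0, baseline = 0)
  tr <- simulate_traces(emb)
  st <- render_frames(emb, tr, nucleus_radius_px = 5, psf_sigma_px = 3)
  q <- quantify_stack(st)
  expect_equal(length(unique(q$nucleus_id)), nrow(emb$nuclei))
  # match measured nuclei to planted ones by position
  q$planted <- vapply(seq_len(nrow(q)), function(i)
    emb$nuclei$nucleus_id[which.min((emb$nuclei$ap_um - q$ap_um[i])^2 +
                                    (emb$nuclei$dv_um - q$dv_um[i])^2)],
    integer(1))
  truth <- tr[, c("nucleus_id", "frame", "fluor_ms2", "true_state")]
  q$frame0 <- q$frame - 1
  mg <- merge(q, truth, by.x = c("planted", "frame0"),
              by.y = c("nucleus_id", "frame"))
  on <- mg$true_state == 1
  expect_true(any(on))
  expect_true(all(abs(mg$fluor_ms2.x[on] - mg$fluor_ms2.y[on]) /
                  mg$fluor_ms2.y[on] < 0.05))
  expect_true(all(mg$fluor_ms2.x[!on] < 30))  # OFF frames below threshold
})
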