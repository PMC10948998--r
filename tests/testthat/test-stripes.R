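test_that("well-separated bands become ordered mature stripes", {
  el <- c(outer(seq(0, 3), c(20, 30, 40, 50, 60, 70, 80), "+"))  # 7 bands
  d <- define_mature_stripes(el, gap_min = 5, min_cluster = 3)
  expect_equal(d$stripe_id, 1:7)
  expect_equal(d$anterior, c(20, 30, 40, 50, 60, 70, 80))
  expect_equal(d$posterior, c(23, 33, 43, 53, 63, 73, 83))
  expect_equal(d$domain_start, d$anterior)
  expect_equal(d$domain_end, c(d$anterior[-1], 100))

  d2 <- define_mature_stripes(c(10, 11, 12, 40, 41, 42), gap_min = 5)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$domain_end, c(40, 100))  # only the last domain runs to 100
  expect_error(define_mature_stripes(numeric(0)), "no mature stripes")
})

test_that("gap clustering agrees with a brute-force split oracle", {
  set.seed(61)
  for (trial in 1:30) {
    el <- sort(runif(sample(10:60, 1), 0, 100))
    gap_min <- runif(1, 1, 8)
    d <- tryCatch(define_mature_stripes(el, gap_min, min_cluster = 2),
                  error = function(e) NULL)
    o <- oracle_gap_split(el, gap_min, min_cluster = 2)
    if (is.null(d)) {
      expect_equal(length(o), 0)
    } else {
      expect_equal(nrow(d), length(o))
      for (k in seq_along(o)) {
        expect_equal(d$anterior[k], o[[k]][1])
        expect_equal(d$posterior[k], o[[k]][2])
      }
    }
  }
})

test_that("nuclei map to half-open stripe domains", {
  d <- define_mature_stripes(c(30, 31, 32, 50, 51, 52), gap_min = 5)
  # domain 1 = [30, 50), domain 2 = [50, 100]
  expect_equal(assign_nuclei_to_stripes(d, c(30, 49.9, 50, 99, 100, 29.9)),
               c(1L, 1L, 2L, 2L, 2L, NA))
  bad <- d
  bad$domain_end[1] <- 60  # overlaps domain 2
  expect_error(assign_nuclei_to_stripes(bad, 50), "overlap")
})

test_that("domain assignment matches brute-force interval lookup", {
  tr <- simulate_traces(embryo_sim("wt", seed = 31))
  rec <- analyze_embryo(tr)
  sid <- assign_nuclei_to_stripes(rec$domains, rec$nt$el_pct)
  for (i in seq_along(sid)) {
    x <- rec$nt$el_pct[i]
    expected <- NA_integer_
    for (k in seq_len(nrow(rec$domains))) {
      hi_ok <- if (k == nrow(rec$domains)) x <= rec$domains$domain_end[k]
      else x < rec$domains$domain_end[k]
      if (x >= rec$domains$domain_start[k] && hi_ok)
        expected <- rec$domains$stripe_id[k]
    }
    expect_identical(sid[i], expected)
  }
  # domains tile: every last-frame active nucleus belongs to exactly one
  last_active <- which(rec$nt$active[, 100])
  expect_false(anyNA(sid[last_active]))
})

test_that("boundary_track recovers a rectangular stripe exactly", {
  el <- rep(seq(10, 90, by = 5), each = 5)
  dv <- rep(seq(-100, 100, by = 50), times = 17)
  active <- matrix(FALSE, length(el), 10)
  stripe_nuc <- el >= 40 & el <= 60
  active[stripe_nuc, 3:10] <- TRUE
  nt <- make_nt(el, dv, active)
  d <- data.frame(stripe_id = 1L, anterior = 40, posterior = 60,
                  n_nuclei = sum(stripe_nuc), domain_start = 0,
                  domain_end = 100)
  bt <- boundary_track(nt, d, n_sections = 5, el_per_nucleus = 5)
  on_t <- bt$t_norm >= nt$t_norm[3]
  expect_true(all(bt$anterior[on_t] == 40))
  expect_true(all(bt$posterior[on_t] == 60))
  expect_true(all(bt$width_el[on_t] == 20))
  expect_true(all(bt$width_nuclei[on_t] == 4))
  expect_true(all(bt$position[on_t] == 50))
  expect_true(all(is.na(bt$anterior[!on_t])))
  expect_error(boundary_track(nt, d, n_sections = 0), ">= 1")
})

test_that("empty DV sections are dropped from the boundary mean", {
  # stripe active in sections 1-3 only (dv < 0); asymmetric extents
  el <- c(40, 50, 60, 45, 55)
  dv <- c(-100, -60, -20, 20, 60)
  active <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE), 5, 4)
  nt <- make_nt(el, dv, active)
  d <- data.frame(stripe_id = 1L, anterior = 40, posterior = 60,
                  n_nuclei = 3, domain_start = 0, domain_end = 100)
  bt <- boundary_track(nt, d, n_sections = 5, el_per_nucleus = 1,
                       dv_range = c(-100, 100))
  # three singleton sections: mean of (40, 50, 60) on both sides
  expect_true(all(bt$anterior == 50))
  expect_true(all(bt$posterior == 50))
})

test_that("boundary_track equals the per-section min/max oracle", {
  set.seed(71)
  for (trial in 1:8) {
    n <- 150
    el <- runif(n, 0, 100)
    dv <- runif(n, -120, 120)
    active <- matrix(runif(n * 12) < 0.4, n, 12)
    d <- define_mature_stripes(el[active[, 12]], gap_min = 6, min_cluster = 2)
    nt <- make_nt(el, dv, active)
    bt <- boundary_track(nt, d, n_sections = 5, el_per_nucleus = 1)
    o <- oracle_boundaries(el, dv, active, d, n_sections = 5)
    for (k in seq_len(nrow(d))) {
      b <- bt[bt$stripe_id == d$stripe_id[k], ]
      expect_equal(b$anterior, o[[k]]$anterior, tolerance = 1e-12)
      expect_equal(b$posterior, o[[k]]$posterior, tolerance = 1e-12)
    }
  }
})

test_that("summarize_window averages the late-NC14 grid points", {
  t100 <- seq(0, 1, length.out = 100)
  bt <- data.frame(stripe_id = 1L, t_norm = t100, anterior = 40,
                   posterior = 40 + t100, width_el = t100,
                   width_nuclei = t100, position = 40 + t100 / 2,
                   n_active = 1L)
  class(bt) <- c("boundary_track", "data.frame")
  s <- summarize_window(bt, c(0.80, 0.90))
  sel <- t100 >= 0.80 - 1e-9 & t100 <= 0.90 + 1e-9
  expect_equal(s$width_el, mean(t100[sel]), tolerance = 1e-12)
  expect_equal(s$width_el, 0.85, tolerance = 5e-3)  # grid-quantized midpoint
  # constant width: summary equals the constant
  bt$width_el <- 7
  expect_equal(summarize_window(bt)$width_el, 7)
})

test_that("stripe2_expansion sees a planted constant width offset", {
  t100 <- seq(0, 1, length.out = 100)
  mk <- function(width) {
    bt <- data.frame(stripe_id = 2L, t_norm = t100, anterior = 38,
                     posterior = 38 + width, width_el = width,
                     width_nuclei = width, position = 38 + width / 2,
                     n_active = 10L)
    class(bt) <- c("boundary_track", "data.frame")
    attr(bt, "el_per_nucleus") <- 1
    bt
  }
  wt <- list(mk(4), mk(4))
  expect_equal(stripe2_expansion(wt, wt), 0)
  het <- list(mk(5.6), mk(5.6))
  expect_equal(stripe2_expansion(wt, het), 1.6)
  expect_error(stripe2_expansion(list(), het), "nonempty")
})

test_that("activation kinetics cross the onset fraction where planted", {
  el <- rep(c(45, 50, 55), each = 4)
  dv <- rep(c(-30, -10, 10, 30), times = 3)
  active <- matrix(FALSE, 12, 100)
  active[, 51:100] <- TRUE  # step activation at t = 0.505
  nt <- make_nt(el, dv, active)
  d <- data.frame(stripe_id = 1L, anterior = 45, posterior = 55,
                  n_nuclei = 12, domain_start = 40, domain_end = 60)
  kin <- activation_kinetics(nt, d)
  expect_equal(onset_time(kin, 1), nt$t_norm[51])
  expect_equal(max(kin$frac_active), 1)
  # all-on from the start
  nt2 <- make_nt(el, dv, matrix(TRUE, 12, 100))
  expect_equal(onset_time(activation_kinetics(nt2, d), 1), 0)
  # never crossing: undefined onset and delay
  nt3 <- make_nt(el, dv, matrix(FALSE, 12, 100))
  kin3 <- activation_kinetics(nt3, d)
  expect_true(is.na(onset_time(kin3, 1)))
  expect_true(is.na(onset_delay(kin, kin3, 1)))
  expect_equal(onset_delay(kin, kin, 1, nc14_duration = 3050), 0)
})

test_that("interstripe distance is the midpoint separation", {
  t100 <- seq(0, 1, length.out = 100)
  bt <- rbind(
    data.frame(stripe_id = 1L, t_norm = t100, anterior = 38, posterior = 42,
               width_el = 4, width_nuclei = 4, position = 40, n_active = 5L),
    data.frame(stripe_id = 2L, t_norm = t100, anterior = 58, posterior = 62,
               width_el = 4, width_nuclei = 4, position = 60, n_active = 5L))
  class(bt) <- c("boundary_track", "data.frame")
  d <- interstripe_distance(bt, 1, 2)
  expect_true(all(d$distance == 20))
  expect_true(all(interstripe_distance(bt, 1, 1)$distance == 0))
})

test_that("aligned output profiles drop sparse bins and keep uniform means", {
  nuclei <- data.frame(embryo_id = rep(1:2, each = 36),
                       el_pct = rep(c(seq(40, 45.5, by = 0.5),
                                      seq(42, 47.5, by = 0.5)), each = 3),
                       output = 3.3)
  prof <- aligned_output_profile(nuclei, bin_el = 1, min_n = 10)
  expect_gt(nrow(prof), 0)
  expect_true(all(prof$mean_output == 3.3))
  expect_true(all(prof$n >= 10))
  # a pooled bin with 9 nuclei is excluded
  nine <- data.frame(embryo_id = 1, el_pct = c(rep(40.2, 10), rep(41.3, 9)),
                     output = 1)
  prof9 <- aligned_output_profile(nine, bin_el = 1, min_n = 10)
  expect_equal(prof9$rel_el, 0)  # only the 10-nucleus bin survives
  expect_error(aligned_output_profile(nine[0, ]), "empty stripe")
})

test_that("aligned profiles recover a planted linear repression gradient", {
  set.seed(83)
  slope <- -2
  nuclei <- do.call(rbind, lapply(1:3, function(e) {
    start <- 40 + runif(1, -1, 1)       # embryo-specific stripe origin
    el <- start + rep(seq(0, 7.5, by = 0.5), each = 4)
    data.frame(embryo_id = e, el_pct = el,
               output = 100 + slope * (el - start) + rnorm(length(el), 0, 1))
  }))
  prof <- aligned_output_profile(nuclei, bin_el = 1, min_n = 10)
  fit <- stats::lm(mean_output ~ rel_el, data = prof)
  expect_lt(abs(coef(fit)[2] - slope) / abs(slope), 0.1)
})

test_that("profile threshold boundaries scan first/last crossing bins", {
  p <- bin_profile(rep(1, 10), seq(61, 79, by = 2), n_bins = 50)
  b <- profile_boundaries_by_threshold(p, 0.5)
  expect_equal(unname(b), c(60, 80))
  p0 <- bin_profile(rep(0, 10), seq(61, 79, by = 2), n_bins = 50)
  expect_true(all(is.na(profile_boundaries_by_threshold(p0, 0.5))))
  set.seed(89)
  for (trial in 1:20) {
    vals <- runif(50, 0, 1)
    pr <- data.frame(bin_lo = seq(0, 98, by = 2), bin_hi = seq(2, 100, by = 2),
                     bin_mid = seq(1, 99, by = 2), bin_mean = vals,
                     bin_count = 5L)
    th <- runif(1, 0, 1)
    b <- profile_boundaries_by_threshold(pr, th)
    above <- which(vals > th)
    if (length(above) == 0) expect_true(all(is.na(b)))
    else expect_equal(unname(b), c(pr$bin_lo[min(above)], pr$bin_hi[max(above)]))
  }
})
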