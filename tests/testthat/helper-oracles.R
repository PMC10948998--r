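# Independent brute-force oracles.  These deliberately use naive loops and
# a different code path from the package implementations.

oracle_top2 <- function(values) {
  v <- sort(values, decreasing = TRUE)
  mean(v[seq_len(min(2, length(v)))])
}

oracle_trapz <- function(f, t) {
  ok <- !is.na(f)
  f <- f[ok]; t <- t[ok]
  if (length(f) < 2) return(NA_real_)
  s <- 0
  for (i in seq_len(length(f) - 1))
    s <- s + (t[i + 1] - t[i]) * (f[i] + f[i + 1]) / 2
  s
}

oracle_interp <- function(tt, y, tout) {
  out <- rep(NA_real_, length(tout))
  for (k in seq_along(tout)) {
    x <- tout[k]
    if (x < min(tt) || x > max(tt)) next
    i <- max(which(tt <= x))
    if (tt[i] == x) { out[k] <- y[i]; next }
    out[k] <- y[i] + (y[i + 1] - y[i]) * (x - tt[i]) / (tt[i + 1] - tt[i])
  }
  out
}

oracle_bin_means <- function(values, el, n_bins) {
  w <- 100 / n_bins
  means <- counts <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * w; hi <- b * w
    inb <- if (b == n_bins) el >= lo & el <= hi else el >= lo & el < hi
    inb <- inb & !is.na(values)
    counts[b] <- sum(inb)
    means[b] <- if (counts[b] > 0) mean(values[inb]) else NA_real_
  }
  list(means = means, counts = counts)
}

oracle_cv <- function(mat) {
  cv <- rep(NA_real_, ncol(mat))
  for (b in seq_len(ncol(mat))) {
    v <- mat[, b][!is.na(mat[, b])]
    if (length(v) >= 2 && mean(v) > 0) cv[b] <- stats::sd(v) / mean(v)
  }
  cv
}

oracle_gap_split <- function(el, gap_min, min_cluster) {
  x <- sort(el)
  clusters <- list(x[1])
  for (i in seq_along(x)[-1]) {
    if (x[i] - x[i - 1] > gap_min) clusters <- c(clusters, list(x[i]))
    else clusters[[length(clusters)]] <- c(clusters[[length(clusters)]], x[i])
  }
  clusters <- Filter(function(cl) length(cl) >= min_cluster, clusters)
  lapply(clusters, range)
}

# boundary positions per stripe and time: per DV section min/max of the
# active member nuclei, then mean over nonempty sections
oracle_boundaries <- function(el, dv, active, domains, n_sections) {
  edges <- seq(min(dv), max(dv), length.out = n_sections + 1)
  res <- list()
  for (k in seq_len(nrow(domains))) {
    lo <- domains$domain_start[k]; hi <- domains$domain_end[k]
    last <- k == nrow(domains)
    member <- el >= lo & (if (last) el <= hi else el < hi)
    ant <- post <- rep(NA_real_, ncol(active))
    for (ti in seq_len(ncol(active))) {
      a_s <- p_s <- c()
      for (s in seq_len(n_sections)) {
        in_s <- if (s == n_sections) dv >= edges[s] & dv <= edges[s + 1]
        else dv >= edges[s] & dv < edges[s + 1]
        act <- which(member & in_s & !is.na(active[, ti]) & active[, ti])
        if (length(act)) {
          a_s <- c(a_s, min(el[act])); p_s <- c(p_s, max(el[act]))
        }
      }
      if (length(a_s)) { ant[ti] <- mean(a_s); post[ti] <- mean(p_s) }
    }
    res[[k]] <- list(anterior = ant, posterior = post)
  }
  res
}

oracle_background_subtract <- function(raw, mid) {
  bg <- Inf
  for (i in seq_along(raw))
    if (mid[i] >= 10 && mid[i] <= 90 && !is.na(raw[i]) && raw[i] < bg)
      bg <- raw[i]
  list(background = bg, corrected = raw - bg)
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
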