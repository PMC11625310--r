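# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive route (loops, enumeration, direct formulas) kept
# separate from the package's own code paths.

# Brute-force Otsu: scan every candidate threshold bin, computing the
# between-class variance with explicit loops over the histogram.
oracle_otsu_bin <- function(counts) {
  n <- sum(counts)
  best <- -Inf
  best_t <- NA_integer_
  nb <- length(counts)
  for (t in 0:(nb - 2L)) {
    c0 <- counts[seq_len(t + 1L)]
    c1 <- counts[(t + 2L):nb]
    w0 <- sum(c0) / n
    w1 <- sum(c1) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * (seq_len(t + 1L) - 1L)) / sum(c0)
    mu1 <- sum(c1 * ((t + 1L):(nb - 1L))) / sum(c1)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# Naive two-pass Pearson r over the pixels of each labelled object.
oracle_pearson_per_object <- function(lab, a, b) {
  k <- max(lab)
  r <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    sel <- lab == i
    x <- a[sel]; y <- b[sel]
    mx <- mean(x); my <- mean(y)
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    if (den > 0) r[i] <- sum((x - mx) * (y - my)) / den
  }
  r
}

# Exact Mann-Whitney two-sided p by full enumeration of the C(n, na)
# group assignments of the pooled (tie-free) sample.
oracle_mw_exact_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  combs <- utils::combn(length(pool), na)
  us <- apply(combs, 2, function(ix) {
    x <- pool[ix]; y <- pool[-ix]
    sum(outer(x, y, `>`))
  })
  u_obs <- sum(outer(a, b, `>`))
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Kruskal-Wallis H by the direct rank-sum formula (no ties).
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  offs <- cumsum(c(0, lengths(groups)))
  h <- 0
  for (i in seq_along(groups)) {
    ri <- rk[(offs[i] + 1):offs[i + 1]]
    h <- h + sum(ri)^2 / length(ri)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

# Match ground-truth objects to detected labels by majority overlap and
# report per-object IoU and relative area error.
match_truth_to_detected <- function(truth_lab, det_lab) {
  k <- max(truth_lab)
  out <- data.frame(truth = seq_len(k), iou = 0, area_rel_err = Inf)
  for (i in seq_len(k)) {
    tp <- truth_lab == i
    hit <- det_lab[tp]
    hit <- hit[hit > 0]
    if (!length(hit)) next
    lab <- as.integer(names(sort(table(hit), decreasing = TRUE))[1])
    dp <- det_lab == lab
    out$iou[i] <- sum(tp & dp) / sum(tp | dp)
    out$area_rel_err[i] <- abs(sum(dp) - sum(tp)) / sum(tp)
  }
  out
}

# A flat-background image with axis-aligned rectangles of given exact
# pixel counts (rows x cols factor pairs), spaced apart.
rect_scene <- function(px_counts, shapes, value = 1, nr = 256, nc = 256,
                       pixel_size = 0.11) {
  m <- matrix(0, nr, nc)
  lab <- matrix(0L, nr, nc)
  at <- 20
  for (i in seq_along(px_counts)) {
    h <- shapes[[i]][1]; w <- shapes[[i]][2]
    stopifnot(h * w == px_counts[i])
    m[at:(at + h - 1), at:(at + w - 1)] <- value
    lab[at:(at + h - 1), at:(at + w - 1)] <- i
    at <- at + max(h, w) + 15
  }
  list(img = micro_image(m, pixel_size), labels = label_mask(lab, pixel_size))
}
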