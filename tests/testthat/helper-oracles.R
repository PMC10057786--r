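# Independent oracles used across the suite.

# Closed-form mass of a Gaussian component inside a temperature window,
# truncated to the ramp [200, 650] and renormalised the way a finite ramp
# integration sees it.
gaussian_window_mass <- function(center, sigma, lo, hi,
                                 ramp = c(200, 650)) {
  lo <- max(lo, ramp[1]); hi <- min(hi, ramp[2])
  pnorm(hi, center, sigma) - pnorm(lo, center, sigma)
}

# Expected node percentages for a Gaussian-mixture composition (CDF oracle).
oracle_node_pct <- function(centers, sigmas, fractions,
                            breaks = c(200, 340, 400, 460, 650)) {
  masses <- vapply(seq_len(4), function(k) {
    sum(fractions * mapply(gaussian_window_mass, centers, sigmas,
                           MoreArgs = list(lo = breaks[k], hi = breaks[k + 1])))
  }, numeric(1))
  100 * masses / sum(masses)
}

# Brute-force per-pixel loop for stack statistics.
brute_stack_stats <- function(nbr_layers) {
  d <- dim(nbr_layers[[1]])
  mn <- matrix(NA_real_, d[1], d[2])
  s <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- vapply(nbr_layers, function(m) m[i, j], numeric(1))
      v <- v[!is.na(v)]
      if (length(v) >= 1) mn[i, j] <- mean(v)
      if (length(v) >= 2) s[i, j] <- sd(v)
    }
  }
  list(mean = mn, sd = s)
}

# Brute-force point-to-polyline distance via dense sampling of the lines.
brute_line_distance <- function(px, py, lines, n_per_seg = 20001) {
  best <- Inf
  for (l in lines) {
    for (k in seq_len(nrow(l) - 1)) {
      t <- seq(0, 1, length.out = n_per_seg)
      xs <- l[k, 1] + t * (l[k + 1, 1] - l[k, 1])
      ys <- l[k, 2] + t * (l[k + 1, 2] - l[k, 2])
      best <- min(best, sqrt((xs - px)^2 + (ys - py)^2))
    }
  }
  best
}

# Tie-corrected Kruskal-Wallis H computed directly from the defining
# rank formula (independent of stats::kruskal.test).
brute_kruskal_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  t <- table(values)
  h / (1 - sum(t^3 - t) / (N^3 - N))
}

# Mean thermal index over a core's upper-50 cm (or deepest-50 cm) measured
# samples, via the rockeval pipeline.
core_index_mean <- function(core, what = "i_index", where = "upper") {
  segs <- core$segments
  keep <- if (where == "upper") segs$bottom_cm <= 50 else
    segs$top_cm >= max(segs$bottom_cm) - 50
  ids <- segs$sample_id[segs$measured & keep]
  res <- rockeval_table(core$pyrograms[ids])
  mean(res[[what]])
}

# Small scene stack built directly from chosen NBR values (one matrix per
# year): bands are backed out so that nbr(nir, swir2) returns them exactly.
stack_from_nbr <- function(nbr_layers, years = seq_along(nbr_layers) + 2000,
                           res_m = 30) {
  nir <- lapply(nbr_layers, function(m) 0.25 * (1 + m))
  swir2 <- lapply(nbr_layers, function(m) 0.25 * (1 - m))
  scene_stack(years, nir, swir2, res_m = res_m)
}
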