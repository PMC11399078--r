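# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's KD-tree code paths.

brute_cross_nnd <- function(ref, target) {
  apply(ref, 1, function(p) {
    min(sqrt((target[, 1] - p[1])^2 + (target[, 2] - p[2])^2))
  })
}

brute_self_nnd <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  apply(d, 1, min)
}

# One-to-one greedy matching of ground-truth positions to recovered centers
# within a distance threshold; returns the matched fraction of truths.
match_fraction <- function(truth_xy, center_xy, threshold) {
  if (nrow(center_xy) == 0) return(0)
  d <- FNN::get.knnx(center_xy, truth_xy, k = 1)
  ok <- d$nn.dist[, 1] <= threshold
  # one-to-one: a center may serve at most one truth
  matched <- !duplicated(d$nn.index[, 1]) & ok
  mean(matched)
}

# Gaussian localization cloud around a center, constant precision.
make_cloud <- function(cx, cy, n, sigma, frame_range = c(0L, 9999L)) {
  data.frame(frame = sample(seq(frame_range[1], frame_range[2]), n, replace = TRUE),
             x = cx + rnorm(n, 0, sigma), y = cy + rnorm(n, 0, sigma),
             photons = rep(1000, n), lpx = rep(sigma, n), lpy = rep(sigma, n))
}

locs_from_df <- function(df, channel = "test") {
  localization_table(frame = df$frame, x = df$x, y = df$y, photons = df$photons,
                     lpx = df$lpx, lpy = df$lpy, channel_label = channel)
}

# Combine the two partner fields of simulate_dimers into one
# single-channel field (pairing preserved).
.rbind2_single <- function(d) {
  paintquant:::.point_field(
    c(d$a$x, d$b$x), c(d$a$y, d$b$y),
    population = c(d$a$population, d$b$population),
    pair_id = c(d$a$pair_id, d$b$pair_id),
    channel = "single", roi = attr(d$a, "roi"))
}

rand_locs <- function(n, extent = 1000) {
  data.frame(frame = sample.int(1000, n, replace = TRUE) - 1L,
             x = runif(n, 0, extent), y = runif(n, 0, extent),
             photons = rexp(n, 1 / 2000),
             lpx = runif(n, 2, 8), lpy = runif(n, 2, 8))
}
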