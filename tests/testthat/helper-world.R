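# Small shared fixtures, built in code and cached per test run.

tiny_config <- function(seed = 1L, ...) {
  sim_config(boundary = default_boundary(width = 4, height = 4),
             raster_res = 0.2, n_settlements = 120, n_clusters = 60,
             spatial_range = 120, spatial_sd = 0.8, seed = seed, ...)
}

.world_cache <- new.env()

tiny_world <- function(seed = 1L) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]])) {
    cfg <- tiny_config(seed)
    L <- simulate_landscape(cfg)
    S <- simulate_settlements(cfg$boundary, cfg$n_settlements, cfg$seed)
    W <- simulate_survey(S, L, cfg)
    .world_cache[[key]] <- list(config = cfg, landscape = L, settlements = S, world = W)
  }
  .world_cache[[key]]
}

# O(n^2) reference semivariogram: plain double loop.
brute_semivariogram <- function(values, coords, n_bins, max_dist) {
  n <- length(values)
  edges <- seq(0, max_dist, length.out = n_bins + 1)
  cnt <- numeric(n_bins); ssum <- numeric(n_bins)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d > 0 && d <= max_dist) {
      b <- min(max(which(edges < d | (d == 0 & edges == 0))), n_bins)
      b <- min(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
      cnt[b] <- cnt[b] + 1
      ssum[b] <- ssum[b] + (values[i] - values[j])^2
    }
  }
  list(gamma_hat = ifelse(cnt > 0, ssum / (2 * cnt), NA_real_), pair_count = cnt)
}

# All-pairs reference AUC with half-weight ties.
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
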