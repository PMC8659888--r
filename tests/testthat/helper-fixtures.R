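# Shared helpers: tiny network configurations and brute-force oracles.

# A small five-block configuration that exercises every architectural
# element at a fraction of the reference cost.
tiny_config <- function(...) {
  args <- list(growth_rate = 3L, layers_per_block = 2L, n_blocks = 5L,
               drop_rate = 0,
               transition_out_channels = c(6L, 7L, 8L, 9L, 5L),
               stem_channels = 4L, bottleneck_channels = 3L,
               ppm_bins = c(1L, 2L), ppm_branch_channels = 2L,
               skip_channels = 4L, decoder_channels = 5L)
  over <- list(...)
  if (!is.null(over$n_blocks) && is.null(over$transition_out_channels))
    args$transition_out_channels <- NULL
  args[names(over)] <- over
  do.call(dcnet_config, args)
}

random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Naive per-pixel loop oracles, deliberately independent of the vectorized
# implementations.
oracle_counts <- function(P, G) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(P)) {
    if (P[i] == 1 && G[i] == 1) tp <- tp + 1L
    else if (P[i] == 1) fp <- fp + 1L
    else if (G[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_weighted_ce <- function(P, G, lambda = 1) {
  V <- length(P)
  VP1 <- max(sum(P), sum(G == 1), 1e-6 * V, 1)
  omega <- (V - VP1) / VP1
  s <- 0
  for (i in seq_along(P)) {
    p <- min(max(P[i], 1e-6), 1 - 1e-6)
    s <- s + lambda * omega * G[i] * log(p) + (1 - G[i]) * log(1 - p)
  }
  -s / V
}

oracle_gdl <- function(P, G) {
  V <- length(P)
  g1 <- sum(G == 1); g0 <- V - g1
  w1 <- if (g1 > 0) 1 / g1 else 1e6 / V
  w0 <- if (g0 > 0) 1 / g0 else 1e6 / V
  i1 <- i0 <- p1 <- p0 <- 0
  for (i in seq_along(P)) {
    i1 <- i1 + P[i] * G[i]
    i0 <- i0 + (1 - P[i]) * (1 - G[i])
    p1 <- p1 + P[i]
    p0 <- p0 + (1 - P[i])
  }
  1 - 2 * (w1 * i1 + w0 * i0) / (w1 * (p1 + g1) + w0 * (p0 + g0))
}
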