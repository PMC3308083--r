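# Shared fixtures and independent oracles.

tiny_config <- function(seed = 11, ...) {
  sim_config(n_incidence = 4, n_control = 3, n_slices = 2,
             image_shape = c(48, 48), seed = seed, ...)
}

# Brute-force GLCM by explicit double-loop pair enumeration; independent of
# the vectorised implementation.
glcm_oracle <- function(q, mask, offset, orientation, symmetric, n_levels) {
  d <- switch(as.character(orientation),
              "0" = c(0L, 1L), "45" = c(-1L, 1L),
              "90" = c(-1L, 0L), "135" = c(-1L, -1L)) * offset
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + d[1]
      c2 <- cc + d[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!mask[r, cc] || !mask[r2, c2]) next
      if (is.na(q[r, cc]) || is.na(q[r2, c2])) next
      counts[q[r, cc] + 1, q[r2, c2] + 1] <-
        counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  list(p = if (total > 0) counts / total else counts, pair_count = total)
}

oracle_entropy <- function(p) {
  v <- p[p > 0]
  sum(-v * log(v))
}

oracle_contrast <- function(p) {
  g <- seq_len(nrow(p)) - 1
  sum(p * outer(g, g, function(i, j) (i - j)^2))
}

oracle_variance <- function(p) {
  g <- seq_len(nrow(p)) - 1
  mu <- sum(rowSums(p) * g)
  sum(rowSums(p) * (g - mu)^2)
}

# Rician magnitude draw for a noise-free signal vector
rician <- function(signal, sigma) {
  sqrt((signal + stats::rnorm(length(signal), 0, sigma))^2 +
         stats::rnorm(length(signal), 0, sigma)^2)
}

# a synthetic t2_map-shaped object from bare arrays
fake_t2_map <- function(t2, labels, valid = NULL) {
  if (is.null(valid)) valid <- labels > 0
  list(t2 = t2, valid = valid, labels = labels)
}

# correlated two-rater ordinal table via a shared latent severity
random_ratings <- function(n = 100, k = 4, noise = 0.4) {
  lat <- stats::rnorm(n)
  cuts <- sort(stats::runif(k - 1, -1.5, 1.5))
  r1 <- findInterval(lat + stats::rnorm(n, 0, noise), cuts)
  r2 <- findInterval(lat + stats::rnorm(n, 0, noise), cuts)
  cbind(r1, r2)
}
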