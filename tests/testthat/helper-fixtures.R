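# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# tiny deterministic map: one vessel disc in a small domain
tiny_map <- function(n = 32, pixel_um = 25, ci = NULL, cj = NULL, r = 2.2) {
  ci <- if (is.null(ci)) (n + 1) / 2 else ci
  cj <- if (is.null(cj)) (n + 1) / 2 else cj
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
  vessel_map(m, pixel_size_um = pixel_um)
}

# two-pixel domain: one vessel pixel, one tissue pixel (single-voxel CRD)
single_voxel_map <- function(pixel_um = 10) {
  m <- matrix(c(TRUE, FALSE), 1, 2)
  vessel_map(m, pixel_size_um = pixel_um)
}

# mid-size clustered synthetic map at the test resolution
test_synth_map <- function(vf, seed, n = 128, pixel_um = 12.5) {
  generate_synthetic_map(synthetic_vessel_spec(vf, seed = seed),
                         shape = c(n, n), pixel_size_um = pixel_um)
}

# brute-force Euclidean distance transform, O(N * V)
brute_distance <- function(mask, pixel_um) {
  vr <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((vr[, 1] - i)^2 + (vr[, 2] - j)^2))
    }
  }
  out * pixel_um
}

# independently coded Huang fuzzy-entropy exhaustive search on integer
# gray levels 0..255 (the oracle; histogram formulation, all 256 levels).
# Returns the per-split entropies so ties (flat valleys between well
# separated modes) can be handled by value rather than by index.
huang_oracle <- function(img) {
  h <- tabulate(as.integer(img) + 1L, 256L)
  lev <- 0:255
  C <- max(lev[h > 0]) - min(lev[h > 0])
  ss <- rep(NA_real_, 255)
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lev[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * lev[(t + 2):256]) / w1
    mu <- ifelse(lev <= t, mu0, mu1)
    u <- 1 / (1 + abs(lev - mu) / C)
    e <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    ss[t + 1] <- sum(h * e)
  }
  list(best_t = which.min(ss) - 1L, entropy = ss)
}

# brute-force linear convolution oracle (quadruple loop, small grids only)
brute_conv <- function(A, K) {
  ctr <- (dim(K) + 1L) %/% 2L
  D <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    acc <- 0
    for (a in seq_len(nrow(K))) for (b in seq_len(ncol(K))) {
      si <- i - (a - ctr[1]); sj <- j - (b - ctr[2])
      if (si >= 1 && si <= nrow(A) && sj >= 1 && sj <= ncol(A)) {
        acc <- acc + K[a, b] * A[si, sj]
      }
    }
    D[i, j] <- acc
  }
  D
}
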