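# Shared helpers and independent oracles.

# 90-degree counterclockwise index rotation of a matrix.
rot90_ccw <- function(m) t(m[, rev(seq_len(ncol(m))), drop = FALSE])

# 180-degree index rotation.
rot180_idx <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

# Horizontal mirror.
flip_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

# Brute-force circular extrema count: for every sample, compare against its
# circular neighbours after collapsing plateaus by scanning all rotations of
# the run-merged sequence. Used only on hand-built vectors.
brute_extrema <- function(v, eps) {
  P <- length(v)
  # merge circularly adjacent samples within eps, trying every start offset
  # and taking the canonical (first-break) segmentation
  br <- which(abs(v - v[c(P, seq_len(P - 1L))]) > eps)
  if (length(br) == 0L) return(c(0L, 0L))
  idx <- c(br[1L]:P, seq_len(br[1L] - 1L))
  grp <- cumsum(abs(v[idx] - v[c(idx[length(idx)], idx[-length(idx)])]) > eps)
  grp[1L] <- 1L
  w <- as.numeric(tapply(v[idx], grp, mean))
  n <- length(w)
  if (n < 2L) return(c(0L, 0L))
  nmax <- 0L; nmin <- 0L
  for (i in seq_len(n)) {
    l <- w[if (i == 1L) n else i - 1L]
    r <- w[if (i == n) 1L else i + 1L]
    if (w[i] > l && w[i] > r) nmax <- nmax + 1L
    if (w[i] < l && w[i] < r) nmin <- nmin + 1L
  }
  c(nmax, nmin)
}

# Labels implied by a shuffle record: the centred index of the source block
# now sitting at each raster position.
shuffle_truth_labels <- function(grid, record) {
  N <- grid$N
  out <- array(0, c(N, N, 2L))
  for (t in seq_len(N * N)) {
    a <- (t - 1L) %% N + 1L
    b <- (t - 1L) %/% N + 1L
    oa <- (record$permutation[t] - 1L) %% N + 1L
    ob <- (record$permutation[t] - 1L) %/% N + 1L
    out[a, b, ] <- grid$index_coords[oa, ob, ]
  }
  out
}

# A block-constant test image with prescribed per-block means (column-major
# over blocks), block size bs.
block_constant_image <- function(means_by_pos, N, bs = 4L) {
  img <- matrix(0, N * bs, N * bs)
  for (t in seq_len(N * N)) {
    a <- (t - 1L) %% N + 1L
    b <- (t - 1L) %/% N + 1L
    img[((a - 1L) * bs + 1L):(a * bs), ((b - 1L) * bs + 1L):(b * bs)] <-
      means_by_pos[t]
  }
  img
}
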