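# Information preprocessing: N x N block partition with centred indices,
# uniform block shuffling, image rotation, index relabeling under rotation,
# and gray-value matching of shuffled blocks to their original indices.

#' Centred block index coordinates
#'
#' For an N x N partition the block indices are the centred coordinates
#' `{-(N-1)/2, ..., (N-1)/2}` in unit steps (half-integers when N is even),
#' giving exactly N unique symmetric values per axis. The horizontal index i
#' grows with column, the vertical index j upward (decreasing row), matching
#' the Cartesian frame used by the rotation matrices.
#'
#' @param N Blocks per side.
#' @return An N x N x 2 array; `[a, b, ]` is `c(i, j)` for the block in grid
#'   row a, column b.
#' @export
block_index_coords <- function(N) {
  out <- array(0, dim = c(N, N, 2L))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      out[a, b, ] <- c(b - (N + 1) / 2, (N + 1) / 2 - a)
    }
  }
  out
}

#' Partition an image into an N x N block grid
#'
#' The image is centre-cropped to the largest size divisible by N, then split
#' into equal blocks carrying centred index coordinates. Reassembling the
#' blocks reproduces the cropped image bit-exactly.
#'
#' @param image Numeric matrix.
#' @param N Blocks per side, >= 1 and at most the image side.
#' @return An object of class `"block_grid"`: list with `blocks` (N x N list
#'   matrix of patches), `index_coords` ([block_index_coords()]), `block_h`,
#'   `block_w`, `N`, and `image` (the cropped image).
#' @export
partition_blocks <- function(image, N) {
  img <- to_gray(image)
  N <- as.integer(N)
  if (N < 1L) stop("`N` must be >= 1")
  if (N > nrow(img) || N > ncol(img)) stop("`N` larger than the image side")
  bh <- nrow(img) %/% N
  bw <- ncol(img) %/% N
  r0 <- (nrow(img) - bh * N) %/% 2L
  c0 <- (ncol(img) - bw * N) %/% 2L
  img <- img[(r0 + 1L):(r0 + bh * N), (c0 + 1L):(c0 + bw * N), drop = FALSE]
  blocks <- vector("list", N * N)
  dim(blocks) <- c(N, N)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      blocks[[a, b]] <- img[((a - 1L) * bh + 1L):(a * bh),
                            ((b - 1L) * bw + 1L):(b * bw), drop = FALSE]
    }
  }
  structure(
    list(blocks = blocks, index_coords = block_index_coords(N),
         block_h = bh, block_w = bw, N = N, image = img),
    class = "block_grid"
  )
}

#' Reassemble a block grid into an image
#'
#' @param grid A `"block_grid"`.
#' @param order Optional integer vector: `order[t]` is the source block
#'   (raster position, column-major) placed at raster position t. Default is
#'   the identity.
#' @return Numeric matrix.
#' @export
assemble_blocks <- function(grid, order = seq_len(grid$N^2)) {
  N <- grid$N
  out <- matrix(0, grid$block_h * N, grid$block_w * N)
  for (t in seq_len(N * N)) {
    a <- (t - 1L) %% N + 1L
    b <- (t - 1L) %/% N + 1L
    src <- grid$blocks[[order[t]]]
    out[((a - 1L) * grid$block_h + 1L):(a * grid$block_h),
        ((b - 1L) * grid$block_w + 1L):(b * grid$block_w)] <- src
  }
  out
}

#' Shuffle the blocks of a grid uniformly at random
#'
#' Draws a permutation uniformly from all (N^2)! arrangements with the seeded
#' RNG and places each block at its permuted grid position. The pixel multiset
#' is conserved and the record is reproducible from the seed.
#'
#' @param grid A [partition_blocks()] result.
#' @param seed Integer RNG seed.
#' @return An object of class `"shuffle_record"`: list with `permutation`
#'   (`permutation[t]` = raster position of the source block placed at t),
#'   `seed`, and `shuffled_image`.
#' @export
shuffle_blocks <- function(grid, seed) {
  stopifnot(inherits(grid, "block_grid"))
  n <- grid$N^2
  perm <- with_local_seed(seed, sample.int(n))
  structure(
    list(permutation = perm, seed = as.integer(seed),
         shuffled_image = assemble_blocks(grid, perm)),
    class = "shuffle_record"
  )
}

#' Rotation matrix for the k-th scheduled rotation
#'
#' Returns the 2 x 2 rotation matrix with angle `(k - 1) * pi / K`,
#' orthonormal with determinant +1; `k = 1` is the identity.
#'
#' @param k Rotation index, `1 <= k <= K`.
#' @param K Number of scheduled rotations.
#' @return A 2 x 2 numeric matrix.
#' @export
rotation_matrix <- function(k, K) {
  if (k < 1 || k > K) stop("`k` must satisfy 1 <= k <= K")
  angle_matrix((k - 1) * pi / K)
}

angle_matrix <- function(a) {
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Map a block index through a rotation matrix
#'
#' Row-vector convention: `(u, v) = (i, j) %*% R`. The result is continuous
#' and never snapped back to the block grid; rotation by pi/6 or pi/4 yields
#' non-integer labels by design, since the similarity loss is a Euclidean
#' regression.
#'
#' @param index Numeric `c(i, j)`.
#' @param R A 2 x 2 orthonormal matrix.
#' @return Numeric `c(u, v)`.
#' @export
map_block_index <- function(index, R) {
  as.numeric(matrix(index, 1L, 2L) %*% R)
}

#' Rotate an image about its centre
#'
#' Counterclockwise rotation with bilinear interpolation, zero fill outside
#' the source, and unchanged output size. Angles 0 and pi are implemented as
#' exact index operations.
#'
#' @param image Numeric matrix.
#' @param angle Rotation angle in radians.
#' @return Numeric matrix of the same size.
#' @export
rotate_image <- function(image, angle) {
  img <- to_gray(image)
  a <- angle %% (2 * pi)
  if (a == 0) return(img)
  if (isTRUE(all.equal(a, pi))) return(rot180(img))
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rr <- matrix(rep(seq_len(H), times = W), H)
  cy <- cr - rr                       # y up
  cxm <- matrix(rep(seq_len(W), each = H), H) - cc
  # inverse map: source = R(-a) %*% target
  xs <- cxm * cos(a) + cy * sin(a)
  ys <- -cxm * sin(a) + cy * cos(a)
  sc <- xs + cc
  sr <- cr - ys
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, H, W)
}

#' Assign original block indices to shuffled positions by gray-value matching
#'
#' Each original block's mean gray value is compared with the block means of
#' the shuffled image; the original index `(i, j)` is assigned to the shuffled
#' position whose mean is closest. Matching is one-to-one: candidate pairs are
#' taken greedily in ascending order of absolute mean discrepancy (ties broken
#' by raster order), so every shuffled position receives exactly one label.
#' When all block means are distinct this recovers the true inverse
#' permutation.
#'
#' @param original A [partition_blocks()] grid of the original image.
#' @param shuffled A grid of the shuffled image with the same N and block
#'   size.
#' @return An N x N x 2 array: `[m_row, n_col, ]` is the original index
#'   `(i, j)` assigned to that shuffled position.
#' @export
assign_shuffled_indices <- function(original, shuffled) {
  stopifnot(inherits(original, "block_grid"), inherits(shuffled, "block_grid"))
  if (original$N != shuffled$N ||
      original$block_h != shuffled$block_h ||
      original$block_w != shuffled$block_w) {
    stop("grids must have the same N and block size")
  }
  N <- original$N
  n <- N * N
  mo <- vapply(seq_len(n), function(t) mean(original$blocks[[t]]), numeric(1L))
  ms <- vapply(seq_len(n), function(t) mean(shuffled$blocks[[t]]), numeric(1L))
  d <- abs(outer(mo, ms, "-"))
  ord <- order(as.vector(d),
               rep(seq_len(n), times = n),   # original raster position
               rep(seq_len(n), each = n))    # shuffled raster position
  used_o <- logical(n); used_s <- logical(n)
  match_s <- integer(n)  # shuffled position -> original raster position
  for (e in ord) {
    o <- (e - 1L) %% n + 1L
    s <- (e - 1L) %/% n + 1L
    if (!used_o[o] && !used_s[s]) {
      used_o[o] <- TRUE; used_s[s] <- TRUE
      match_s[s] <- o
      if (all(used_s)) break
    }
  }
  out <- array(0, dim = c(N, N, 2L))
  ic <- original$index_coords
  for (s in seq_len(n)) {
    a <- (s - 1L) %% N + 1L
    b <- (s - 1L) %/% N + 1L
    oa <- (match_s[s] - 1L) %% N + 1L
    ob <- (match_s[s] - 1L) %/% N + 1L
    out[a, b, ] <- ic[oa, ob, ]
  }
  out
}

#' Rotation schedule for the augmented training set
#'
#' Either an explicit list of angles for the rotated originals and rotated
#' shuffled images, or the uniform schedule `(k - 1) * pi / K` for
#' `k = 1..K`. The first angle of each list must be 0 so `I_1 = I` and
#' `S_1 = S`. The default is the view set `{I, I_pi/6, I_pi/4, S}`.
#'
#' @param angles_original Angles (radians) for the rotated originals.
#' @param angles_shuffled Angles for the rotated shuffled images.
#' @param K If given, overrides both lists with the uniform schedule of K
#'   rotations for both branches.
#' @return An object of class `"rotation_schedule"` with fields
#'   `angles_original`, `angles_shuffled`, `K1`, `K2`.
#' @export
rotation_schedule <- function(angles_original = c(0, pi / 6, pi / 4),
                              angles_shuffled = 0,
                              K = NULL) {
  if (!is.null(K)) {
    angles_original <- angles_shuffled <- (seq_len(K) - 1) * pi / K
  }
  if (length(angles_original) < 1L || angles_original[1L] != 0) {
    stop("the first original angle must be 0 (I_1 = I)")
  }
  if (length(angles_shuffled) > 0L && angles_shuffled[1L] != 0) {
    stop("the first shuffled angle must be 0 (S_1 = S)")
  }
  structure(
    list(angles_original = angles_original, angles_shuffled = angles_shuffled,
         K1 = length(angles_original), K2 = length(angles_shuffled)),
    class = "rotation_schedule"
  )
}

#' Label normalisation constant
#'
#' Divides the centred block labels by `Z = sqrt(2) * (N - 1) / 2` (the norm
#' of the outermost corner index) so every possible rotated label lies in
#' `[-1, 1]` componentwise, matching the saturating output range of the index
#' prediction head. For N = 1 the single label is 0 and Z is set to 1.
#'
#' @param N Blocks per side.
#' @return Positive scalar.
#' @export
label_norm_constant <- function(N) {
  z <- sqrt(2) * (N - 1) / 2
  if (z == 0) 1 else z
}

#' Build the augmented training set for one image
#'
#' Produces the image group `{I_1..I_K1, S_1..S_K2}` by rotating the original
#' and the block-shuffled image per the schedule, together with the per-block
#' continuous index labels: labels of `I_k` are the centred index coordinates
#' mapped through the k-th rotation matrix; labels of `S_1` come from
#' gray-value matching ([assign_shuffled_indices()]); labels of `S_d` are the
#' `S_1` labels mapped through the d-th rotation matrix.
#'
#' @param image Numeric matrix (single channel).
#' @param class_label Integer class in `1..n_classes`.
#' @param n_classes Number of classes C.
#' @param schedule A [rotation_schedule()].
#' @param N Blocks per side.
#' @param seed Integer seed for the block shuffle.
#' @return An object of class `"augmented_set"`: list with `images` (length
#'   K1 + K2), `labels` (N x N x 2 raw label arrays, one per image), `kind`
#'   (`"original"`/`"shuffled"`), `angles`, `class_label`, `onehot`, `N`,
#'   `Z`, `shuffle` (the [shuffle_blocks()] record, or NULL when K2 = 0).
#' @export
build_augmented_set <- function(image, class_label, n_classes,
                                schedule = rotation_schedule(), N = 6L,
                                seed = 1L) {
  img <- to_gray(image)
  stopifnot(inherits(schedule, "rotation_schedule"))
  grid <- partition_blocks(img, N)
  base <- grid$image  # cropped so blocks tile exactly
  K1 <- schedule$K1; K2 <- schedule$K2
  images <- vector("list", K1 + K2)
  labels <- vector("list", K1 + K2)
  kind <- character(K1 + K2)
  angles <- c(schedule$angles_original, schedule$angles_shuffled)
  ic <- grid$index_coords
  rotate_labels <- function(lab, a) {
    R <- angle_matrix(a)
    out <- lab
    for (p in seq_len(N)) {
      for (q in seq_len(N)) {
        out[p, q, ] <- map_block_index(lab[p, q, ], R)
      }
    }
    out
  }
  for (k in seq_len(K1)) {
    images[[k]] <- rotate_image(base, schedule$angles_original[k])
    labels[[k]] <- rotate_labels(ic, schedule$angles_original[k])
    kind[k] <- "original"
  }
  shuffle <- NULL
  if (K2 > 0L) {
    shuffle <- shuffle_blocks(grid, seed)
    s_grid <- partition_blocks(shuffle$shuffled_image, N)
    s1_labels <- assign_shuffled_indices(grid, s_grid)
    for (d in seq_len(K2)) {
      images[[K1 + d]] <- rotate_image(shuffle$shuffled_image,
                                       schedule$angles_shuffled[d])
      labels[[K1 + d]] <- rotate_labels(s1_labels, schedule$angles_shuffled[d])
      kind[K1 + d] <- "shuffled"
    }
  }
  onehot <- numeric(n_classes)
  onehot[class_label] <- 1
  structure(
    list(images = images, labels = labels, kind = kind, angles = angles,
         class_label = as.integer(class_label), onehot = onehot,
         N = as.integer(N), Z = label_norm_constant(N), shuffle = shuffle),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf(
    "Augmented set: %d views (%d original + %d shuffled), N = %d, class %d\n",
    length(x$images), sum(x$kind == "original"), sum(x$kind == "shuffled"),
    x$N, x$class_label))
  invisible(x)
}
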