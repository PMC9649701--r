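# Synthetic imagery: geometric structure fixtures (step edge, T-type corner,
# Gaussian blob) for the orientation-profile analyses, and seeded toy labeled
# datasets for desk-scale classification experiments.

pixel_grid <- function(size) {
  ctr <- (size + 1) / 2
  off <- seq_len(size) - ctr
  list(x = matrix(rep(off, each = size), size),   # column offset
       y = matrix(rep(-off, times = size), size), # row offset, y up
       center = c((size + 1L) %/% 2L, (size + 1L) %/% 2L))
}

structure_fixture <- function(image, feature_point, truth, params) {
  structure(list(image = image, feature_point = feature_point,
                 truth = truth, params = params),
            class = "structure_fixture")
}

#' @export
print.structure_fixture <- function(x, ...) {
  cat(sprintf("Structure fixture: %s, %d x %d, feature point (%d, %d)\n",
              x$truth, nrow(x$image), ncol(x$image),
              x$feature_point[1L], x$feature_point[2L]))
  invisible(x)
}

#' Generate a step-edge fixture
#'
#' Two half-planes split along a line through the image centre, with a
#' one-pixel linear ramp across the boundary so discrete orientation profiles
#' are smooth enough for extrema counting. An optional Gaussian blur widens
#' the transition further.
#'
#' @param size Image side in pixels (odd sizes put the feature point on the
#'   exact centre pixel).
#' @param orientation Angle of the edge line in radians; `pi/2` is a vertical
#'   edge with the low level on the left.
#' @param levels Numeric `c(low, high)` gray levels in `[0, 1]`. Equal levels
#'   degenerate to a constant image with truth `"none"`.
#' @param blur Standard deviation (pixels) of an optional Gaussian blur; 0
#'   disables it.
#' @return A `"structure_fixture"` with fields `image`, `feature_point`
#'   (centre), `truth`, and `params`.
#' @export
make_step_edge <- function(size = 129L, orientation = pi / 2,
                           levels = c(0.2, 0.8), blur = 0) {
  lo <- levels[1L]; hi <- levels[2L]
  if (lo < 0 || hi > 1 || lo > hi) stop("`levels` must satisfy 0 <= low <= high <= 1")
  g <- pixel_grid(size)
  nrm <- orientation - pi / 2  # normal points to the high side
  d <- g$x * cos(nrm) + g$y * sin(nrm)
  img <- lo + (hi - lo) * clamp01(d + 0.5)
  if (blur > 0) img <- gaussian_blur(img, blur)
  truth <- if (hi > lo) "edge" else "none"
  structure_fixture(img, g$center, truth,
                    list(orientation = orientation, levels = levels, blur = blur))
}

gaussian_blur <- function(img, sd) {
  r <- ceiling(3 * sd)
  k <- stats::dnorm(seq(-r, r), sd = sd)
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  pad <- function(n) c(pmin(r:1, n), seq_len(n), pmax(n - r + 1L, 1L):n)
  xp <- img[pad(H), pad(W)]
  # separable filter, valid region
  tmp <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2L))
  tmp <- t(apply(tmp, 1L, function(row) stats::filter(row, k, sides = 2L)))
  tmp[(r + 1L):(r + H), (r + 1L):(r + W)]
}

#' Generate a T-type (or degenerate) corner fixture
#'
#' Three homogeneous angular sectors meet at the centre pixel. The default arm
#' orientations `c(0, pi/2, pi)` give the canonical T: two collinear arms plus
#' a perpendicular one. Boundaries are anti-aliased by 8 x 8 supersampling.
#'
#' When some gray levels coincide the corresponding boundary rays vanish and
#' the truth label is downgraded accordingly: two surviving collinear rays
#' give an edge, two non-collinear rays an L-type corner (flagged in
#' `params$degenerate`), no surviving ray a constant image.
#'
#' @param size Image side in pixels.
#' @param levels Gray levels `c(g1, g2, g3)` of the sectors between
#'   consecutive sorted arm rays.
#' @param arms Three ray angles (radians) bounding the sectors.
#' @return A `"structure_fixture"`; `feature_point` is the centre pixel.
#' @export
make_t_corner <- function(size = 129L, levels = c(0.1, 0.5, 0.9),
                          arms = c(0, pi / 2, pi)) {
  if (length(levels) != 3L || length(arms) != 3L) {
    stop("`levels` and `arms` must each have 3 entries")
  }
  arms <- sort(arms %% (2 * pi))
  ss <- 8L
  big <- size * ss
  ctr <- (big + 1) / 2
  off <- (seq_len(big) - ctr) / ss
  x <- matrix(rep(off, each = big), big)
  y <- matrix(rep(-off, times = big), big)
  phi <- atan2(y, x) %% (2 * pi)
  sector <- findInterval(phi, arms) # 0 or 3 -> wrap sector
  sector[sector == 0L] <- 3L
  img_big <- matrix(levels[sector], big)
  img <- downsample_mean(img_big, ss)

  # Surviving boundary rays: adjacent sector levels differ across the ray.
  survive <- c(levels[3L] != levels[1L],  # ray arms[1]
               levels[1L] != levels[2L],  # ray arms[2]
               levels[2L] != levels[3L])  # ray arms[3]
  n_surv <- sum(survive)
  degenerate <- n_surv < 3L
  truth <- if (n_surv >= 3L) {
    "corner"
  } else if (n_surv == 2L) {
    a <- arms[survive]
    collinear <- isTRUE(all.equal(abs(((a[1L] - a[2L]) %% (2 * pi))), pi)) ||
      isTRUE(all.equal(((a[2L] - a[1L]) %% (2 * pi)), pi))
    if (collinear) "edge" else "corner"
  } else {
    "none"
  }
  g <- pixel_grid(size)
  structure_fixture(img, g$center, truth,
                    list(levels = levels, arms = arms, degenerate = degenerate))
}

downsample_mean <- function(img, s) {
  H <- nrow(img) %/% s
  W <- ncol(img) %/% s
  dim(img) <- c(s, H, s, W)
  out <- apply(img, c(2L, 4L), mean)
  matrix(out, H, W)
}

#' Generate a Gaussian blob fixture
#'
#' An isotropic Gaussian intensity bump on a constant background. At the blob
#' centre every first-order directional derivative vanishes by radial
#' symmetry while the second-order response is strong at all orientations.
#'
#' @param size Image side in pixels.
#' @param sigma_b Blob standard deviation in pixels, > 0.
#' @param amplitude Peak intensity above background; nonzero.
#' @param background Background gray level.
#' @return A `"structure_fixture"`; warns when the bump is clipped by the
#'   image border (size/2 < 3 sigma_b).
#' @export
make_blob <- function(size = 129L, sigma_b = 4, amplitude = 0.6,
                      background = 0.2) {
  if (sigma_b <= 0) stop("`sigma_b` must be positive")
  if (amplitude == 0) stop("`amplitude` must be nonzero")
  if (size / 2 < 3 * sigma_b) {
    warning("blob is clipped: size/2 < 3 * sigma_b")
  }
  g <- pixel_grid(size)
  img <- background + amplitude * exp(-(g$x^2 + g$y^2) / (2 * sigma_b^2))
  structure_fixture(img, g$center, "blob",
                    list(sigma_b = sigma_b, amplitude = amplitude,
                         background = background))
}

# Render one toy-class silhouette. Classes differ by lobe count and phase of a
# star-shaped polar outline; a fixed two-direction shading ramp across the
# image frame makes block means injective in block position, which both the
# gray-value matching stage and the index-prediction head rely on.
render_shape <- function(size, k_lobes, phase, shift, rot, noise, rng_noise) {
  ss <- 2L
  big <- size * ss
  ctr <- (big + 1) / 2
  off <- (seq_len(big) - ctr) / ss
  x0 <- matrix(rep(off, each = big), big)
  y0 <- matrix(rep(-off, times = big), big)
  x <- x0 - shift[1L]
  y <- y0 - shift[2L]
  xr <- x * cos(rot) + y * sin(rot)
  yr <- -x * sin(rot) + y * cos(rot)
  r <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  r_out <- 0.28 * size * (1 + 0.25 * cos(k_lobes * phi + phase) + 0.12 * sin(phi))
  w <- clamp01(r_out - r + 0.5)  # 1-px soft edge
  xn <- (x0 + size / 2) / size
  yn <- (y0 + size / 2) / size
  fg <- 0.45 + 0.30 * xn + 0.18 * yn
  img <- 0.1 * (1 - w) + fg * w
  img <- downsample_mean(img, ss)
  clamp01(img + noise * rng_noise)
}

#' Generate a seeded toy fine-grained dataset
#'
#' Each class is a distinct parametric star-shaped silhouette (class-specific
#' lobe count and phase) rendered with a fixed shading gradient; images within
#' a class differ by small positional jitter (<= 5 % of the side), rotation
#' jitter (<= 10 degrees), and additive Gaussian noise. The generator is a
#' pure function of its parameters and seed, and emulates few-images-per-class
#' cultivar-style recognition at desk scale.
#'
#' @param n_classes Number of classes C, >= 2.
#' @param n_per_class Images per class, >= 2 (half train, half test).
#' @param size Image side in pixels.
#' @param seed Integer RNG seed.
#' @param jitter_pos Positional jitter as a fraction of `size`.
#' @param jitter_rot Rotation jitter half-range in radians.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @return An object of class `"toy_dataset"`: list with `images` (list of
#'   matrices), `class` (integer labels), `split` (`"train"`/`"test"`),
#'   `n_classes`, and the generator parameters.
#' @export
make_toy_dataset <- function(n_classes = 5L, n_per_class = 10L, size = 64L,
                             seed = 1L, jitter_pos = 0.05,
                             jitter_rot = 10 * pi / 180, noise_sd = 0.02) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2 to allow a split")
  images <- vector("list", n_classes * n_per_class)
  cls <- integer(0)
  split <- character(0)
  with_local_seed(seed, {
    idx <- 0L
    for (c in seq_len(n_classes)) {
      k_lobes <- c + 1L
      phase <- 0.7 * (c - 1L)
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1L
        shift <- stats::runif(2L, -jitter_pos, jitter_pos) * size
        rot <- stats::runif(1L, -jitter_rot, jitter_rot)
        rng_noise <- matrix(stats::rnorm(size * size), size)
        images[[idx]] <- render_shape(size, k_lobes, phase, shift, rot,
                                      noise_sd, rng_noise)
        cls[idx] <- c
        split[idx] <- if (i <= ceiling(n_per_class / 2)) "train" else "test"
      }
    }
  })
  structure(
    list(images = images, class = cls, split = split, n_classes = n_classes,
         size = size, seed = seed,
         params = list(n_per_class = n_per_class, jitter_pos = jitter_pos,
                       jitter_rot = jitter_rot, noise_sd = noise_sd)),
    class = "toy_dataset"
  )
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat(sprintf("Toy dataset: %d classes x %d images, %d x %d px (seed %d)\n",
              x$n_classes, x$params$n_per_class, x$size, x$size, x$seed))
  invisible(x)
}
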