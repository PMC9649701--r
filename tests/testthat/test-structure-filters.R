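# Anisotropic Gaussian directional-derivative filters and the
# orientation-profile analysis of local structures.

test_that("kernel construction satisfies the analytic parities", {
  p <- filter_params()
  for (theta in c(0, 0.7, pi / 3)) {
    k1 <- build_directional_kernel(p, theta, 1)
    k2 <- build_directional_kernel(p, theta, 2)
    expect_lt(abs(sum(k1)), 1e-10)
    expect_lt(abs(sum(k2)), 1e-8)
    # theta + pi: order 1 negates, order 2 unchanged
    expect_lt(max(abs(k1 + build_directional_kernel(p, theta + pi, 1))), 1e-10)
    expect_lt(max(abs(k2 - build_directional_kernel(p, theta + pi, 2))), 1e-10)
  }
  # at theta = 0 the order-1 kernel is odd in x (columns), even in y (rows)
  k0 <- build_directional_kernel(p, 0, 1)
  expect_lt(max(abs(k0 + flip_cols(k0))), 1e-12)
  expect_lt(max(abs(k0 - k0[rev(seq_len(nrow(k0))), ])), 1e-12)
  # rotating the sampling grid by 90 degrees gives the theta = pi/2 kernel
  expect_lt(max(abs(build_directional_kernel(p, pi / 2, 1) - rot90_ccw(k0))),
            1e-8)
})

test_that("invalid filter parameters are rejected", {
  expect_error(filter_params(sigma = -1), "sigma")
  expect_error(filter_params(rho = 0.5), "rho")
  expect_error(filter_params(support_radius = 1), "support_radius")
  expect_error(filter_params(n_orientations = 9), "even")
  expect_error(filter_params(n_orientations = 4), "even|>= 8")
})

test_that("orientation profiles obey derivative parity and border rules", {
  p <- filter_params(n_orientations = 16L)
  expect_error(directional_response(matrix(0.5, 20, 20), c(3, 10), p),
               "border")
  # constant image: identically zero profile (zero-sum kernels)
  pr <- directional_response(matrix(0.7, 20, 20), c(10, 10), p, 1)
  expect_equal(max(abs(pr$responses)), 0)
  set.seed(11)
  img <- matrix(runif(30 * 30), 30)
  half <- p$n_orientations / 2
  for (ord in 1:2) {
    pr <- directional_response(img, c(15, 16), p, ord)
    shifted <- pr$responses[((seq_len(p$n_orientations) - 1 + half) %%
                               p$n_orientations) + 1]
    sgn <- if (ord == 1) -1 else 1
    expect_lt(max(abs(pr$responses - sgn * shifted)), 1e-8)
  }
})

test_that("circular extrema counting handles harmonics, plateaus, constants", {
  th <- 2 * pi * (0:63) / 64
  expect_equal(unname(count_circular_extrema(sin(th))), c(1L, 1L))
  expect_equal(unname(count_circular_extrema(sin(3 * th))), c(3L, 3L))
  expect_equal(unname(count_circular_extrema(rep(0.4, 64))), c(0L, 0L))
  # a 5-sample plateau at the global peak counts once, at every rotation
  base <- sin(th)
  peak <- which.max(base)
  v <- base
  v[((peak - 3):(peak + 1) - 1) %% 64 + 1] <- max(base)
  for (shift in c(0L, 7L, 33L)) {
    vs <- v[((seq_len(64) - 1 + shift) %% 64) + 1]
    got <- count_circular_extrema(vs, eps = 1e-6)
    expect_equal(unname(got), brute_extrema(vs, 1e-6))
    expect_equal(got[["n_maxima"]], 1L)
  }
})

test_that("fixture structures classify as corner, edge, and blob", {
  p <- structure_analysis_params()
  th <- detection_thresholds(p)
  fixtures <- list(corner = make_t_corner(), edge = make_step_edge(),
                   blob = make_blob())
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    lab <- classify_structure(
      directional_response(fx$image, fx$feature_point, p, 1),
      directional_response(fx$image, fx$feature_point, p, 2), th)
    expect_identical(lab$category, nm)
  }
  # corner: three maxima / three minima; edge: one of each
  pr_c <- directional_response(fixtures$corner$image,
                               fixtures$corner$feature_point, p, 1)
  expect_equal(unname(count_circular_extrema(pr_c)), c(3L, 3L))
  pr_e <- directional_response(fixtures$edge$image,
                               fixtures$edge$feature_point, p, 1)
  expect_equal(unname(count_circular_extrema(pr_e)), c(1L, 1L))
  # misuse errors
  expect_error(classify_structure(pr_c, pr_c, th), "order")
  pr_other <- directional_response(fixtures$corner$image, c(40, 40), p, 2)
  expect_error(classify_structure(pr_c, pr_other, th), "location")
})

test_that("response maps agree with point responses and vanish on constants", {
  p <- filter_params(n_orientations = 16L)
  expect_error(response_map(matrix(0, 5, 5), p), "smaller")
  expect_equal(max(abs(response_map(matrix(0.3, 20, 20), p, 1))), 0)
  set.seed(5)
  img <- matrix(runif(24 * 24), 24)
  for (ord in 1:2) {
    stack <- response_map(img, p, ord)
    pr <- directional_response(img, c(12, 13), p, ord)
    expect_lt(max(abs(stack[12, 13, ] - pr$responses)), 1e-10)
  }
  # valid mode masks the border band
  stack <- response_map(img, p, 1, border = "valid")
  R <- p$support_radius
  expect_true(all(is.na(stack[seq_len(R), , ])))
  expect_false(anyNA(stack[(R + 1):(24 - R), (R + 1):(24 - R), ]))
})

test_that("responses are invariant to pi rotation and horizontal flip", {
  p <- filter_params(n_orientations = 16L)
  P <- p$n_orientations
  set.seed(21)
  for (rep in 1:3) {
    img <- matrix(runif(22 * 26), 22)
    for (ord in 1:2) {
      s <- response_map(img, p, ord)
      sr <- response_map(rot180_idx(img), p, ord)
      expect_lt(max(abs(abs(sr[rev(1:22), rev(1:26), ]) - abs(s))), 1e-6)
      sf <- response_map(img[, rev(1:26)], p, ord)
      q <- ((P / 2 - seq_len(P) + 1) %% P) + 1
      expect_lt(max(abs(abs(sf[, rev(1:26), q]) - abs(s))), 1e-6)
    }
  }
})

test_that("responses are linear in brightness and ignore offsets", {
  p <- filter_params(n_orientations = 16L)
  set.seed(31)
  img <- matrix(runif(20 * 20), 20)
  pr <- directional_response(img, c(10, 10), p, 1)$responses
  pr_scaled <- directional_response(3.5 * img, c(10, 10), p, 1)$responses
  expect_equal(pr_scaled, 3.5 * pr, tolerance = 1e-12)
  pr_shift <- directional_response(img + 0.4, c(10, 10), p, 1)$responses
  expect_lt(max(abs(pr_shift - pr)), 1e-10)
})

test_that("horizontal+vertical responses alone cannot separate corner from edge", {
  p <- structure_analysis_params()
  # an L-type corner symmetric about the 45-degree diagonal ...
  corner <- make_t_corner(levels = c(0.5, 0.2, 0.2))
  pc <- directional_response(corner$image, corner$feature_point, p, 1)
  i0 <- 1L
  i90 <- p$n_orientations / 4 + 1L
  expect_lt(abs(pc$responses[i0] - pc$responses[i90]), 1e-10)
  # ... and a diagonal step edge, also diagonal-symmetric; scale its contrast
  # (responses are exactly linear in it) to match the corner's response
  probe <- make_step_edge(orientation = 3 * pi / 4, levels = c(0.2, 0.8))
  pe0 <- directional_response(probe$image, probe$feature_point, p, 1)
  ratio <- pc$responses[i0] / pe0$responses[i0]
  expect_lt(abs(ratio), 1)
  half <- 0.3 * ratio
  edge <- make_step_edge(orientation = 3 * pi / 4,
                         levels = sort(c(0.5 - half, 0.5 + half)))
  pe <- directional_response(edge$image, edge$feature_point, p, 1)
  # the (0, pi/2) response pairs agree ...
  expect_lt(max(abs(pe$responses[c(i0, i90)] - pc$responses[c(i0, i90)])),
            1e-8)
  # ... yet the full profiles tell the structures apart
  expect_gte(count_circular_extrema(pc)[["n_maxima"]], 2L)
  expect_equal(count_circular_extrema(pe)[["n_maxima"]], 1L)
})
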