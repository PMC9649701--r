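# Fixture generators and the toy dataset.

test_that("step-edge fixtures are column-constant and reduce cleanly", {
  e <- make_step_edge(size = 65, orientation = pi / 2, levels = c(0.2, 0.8))
  expect_identical(e$truth, "edge")
  # vertical edge: every column is constant
  expect_equal(max(apply(e$image, 2, function(col) diff(range(col)))), 0)
  expect_equal(range(e$image), c(0.2, 0.8))
  # degenerate levels: constant image, no structure, zero responses
  flat <- make_step_edge(size = 65, levels = c(0.5, 0.5))
  expect_identical(flat$truth, "none")
  p <- structure_analysis_params()
  expect_equal(max(abs(directional_response(flat$image, flat$feature_point,
                                            p, 1)$responses)), 0)
  expect_error(make_step_edge(levels = c(0.8, 0.2)), "levels")
})

test_that("edge analysis is invariant to rotating the fixture by pi", {
  p <- structure_analysis_params()
  e <- make_step_edge(size = 65, orientation = 1.1)
  pr <- directional_response(e$image, e$feature_point, p, 1)
  rot <- rot180_idx(e$image)
  ctr <- c(66L, 66L) - e$feature_point
  pr2 <- directional_response(rot, ctr, p, 1)
  expect_lt(max(abs(abs(pr2$responses) - abs(pr$responses))), 1e-6)
})

test_that("T-corner fixtures expose three lobes and degrade to edges", {
  p <- structure_analysis_params()
  tc <- make_t_corner(size = 65)
  expect_identical(tc$truth, "corner")
  expect_false(tc$params$degenerate)
  expect_equal(unname(count_circular_extrema(
    directional_response(tc$image, tc$feature_point, p, 1))), c(3L, 3L))
  # two equal levels across the collinear pair: a plain step edge
  de <- make_t_corner(size = 65, levels = c(0.4, 0.4, 0.9))
  expect_identical(de$truth, "edge")
  ce <- count_circular_extrema(
    directional_response(de$image, de$feature_point, p, 1))
  expect_equal(unname(ce), c(1L, 1L))
  # all equal: no structure
  expect_identical(make_t_corner(levels = c(0.5, 0.5, 0.5))$truth, "none")
  # horizontal flip preserves the extrema counts
  tcf <- flip_cols(tc$image)
  cf <- count_circular_extrema(
    directional_response(tcf, tc$feature_point, p, 1))
  expect_equal(unname(cf), c(3L, 3L))
})

test_that("blob fixtures are radially symmetric with strong order-2 response", {
  p <- structure_analysis_params()
  b <- make_blob(size = 65, sigma_b = 4)
  expect_identical(b$truth, "blob")
  p1 <- directional_response(b$image, b$feature_point, p, 1)
  expect_lt(max(abs(p1$responses)), 1e-6)
  p2 <- directional_response(b$image, b$feature_point, p, 2)
  expect_true(all(abs(p2$responses) > 0))
  # responses are linear in the bump amplitude
  b2 <- make_blob(size = 65, sigma_b = 4, amplitude = 0.3)
  p2b <- directional_response(b2$image, b2$feature_point, p, 2)
  expect_equal(p2b$responses, p2$responses / 2, tolerance = 1e-10)
  expect_warning(make_blob(size = 33, sigma_b = 10), "clipped")
  expect_error(make_blob(sigma_b = -1), "sigma_b")
})

test_that("every fixture's truth is recovered by the classifier", {
  p <- structure_analysis_params()
  th <- detection_thresholds(p)
  fixtures <- list(make_step_edge(), make_t_corner(), make_blob())
  for (fx in fixtures) {
    lab <- classify_structure(
      directional_response(fx$image, fx$feature_point, p, 1),
      directional_response(fx$image, fx$feature_point, p, 2), th)
    expect_identical(lab$category, fx$truth)
  }
})

test_that("toy datasets are deterministic, balanced, and separable", {
  d1 <- make_toy_dataset(3, 4, size = 32, seed = 11)
  d2 <- make_toy_dataset(3, 4, size = 32, seed = 11)
  expect_identical(d1, d2)
  d3 <- make_toy_dataset(3, 4, size = 32, seed = 12)
  expect_false(identical(d1$images, d3$images))
  expect_equal(as.vector(table(d1$class)), rep(4L, 3))
  expect_equal(as.vector(table(d1$split, d1$class)["train", ]), rep(2L, 3))
  # zero jitter and zero noise: images within a class are identical
  dz <- make_toy_dataset(2, 3, size = 32, seed = 5, jitter_pos = 0,
                         jitter_rot = 0, noise_sd = 0)
  expect_identical(dz$images[[1L]], dz$images[[2L]])
  expect_false(identical(dz$images[[1L]], dz$images[[4L]]))
  # two maximally distinct classes: a 1-NN pixel classifier is perfect
  dd <- make_toy_dataset(2, 8, size = 32, seed = 21)
  train <- which(dd$split == "train")
  test <- which(dd$split == "test")
  flat <- t(vapply(dd$images, as.vector, numeric(32 * 32)))
  pred <- vapply(test, function(i) {
    dd$class[train[which.min(colSums((t(flat[train, ]) - flat[i, ])^2))]]
  }, integer(1L))
  expect_equal(pred, dd$class[test])
  expect_error(make_toy_dataset(1, 4), "n_classes")
  expect_error(make_toy_dataset(3, 1), "n_per_class")
})
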