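# Block partition, uniform shuffle, rotation schedule, index relabeling,
# and gray-value matching.

test_that("partition produces centred indices and reassembles bit-exactly", {
  img <- matrix(seq_len(36) / 36, 6)
  g <- partition_blocks(img, 2)
  expect_equal(g$block_h, 3L)
  expect_equal(sort(unique(as.vector(g$index_coords))), c(-0.5, 0.5))
  expect_identical(assemble_blocks(g), img)
  # N = 1: the whole image, index (0, 0)
  g1 <- partition_blocks(img, 1)
  expect_identical(g1$blocks[[1L]], img)
  expect_equal(as.vector(g1$index_coords), c(0, 0))
  # 384 x 384 with N = 6: 36 blocks of 64 x 64
  g6 <- partition_blocks(matrix(0, 384, 384), 6)
  expect_equal(c(g6$block_h, g6$block_w), c(64L, 64L))
  expect_equal(length(g6$blocks), 36L)
  # non-divisible sides are centre-cropped
  g3 <- partition_blocks(matrix(runif(11 * 13), 11), 3)
  expect_equal(dim(g3$image), c(9L, 12L))
  expect_error(partition_blocks(matrix(0, 4, 4), 5), "larger")
})

test_that("shuffles are seeded, conservative, and invertible", {
  set.seed(2)
  img <- matrix(runif(64), 8)
  g <- partition_blocks(img, 2)
  s1 <- shuffle_blocks(g, 17)
  s2 <- shuffle_blocks(g, 17)
  expect_identical(s1$permutation, s2$permutation)
  expect_identical(s1$shuffled_image, s2$shuffled_image)
  expect_identical(sort(as.vector(s1$shuffled_image)), sort(as.vector(img)))
  # applying the inverse permutation restores the image bit-exactly
  gs <- partition_blocks(s1$shuffled_image, 2)
  expect_identical(assemble_blocks(gs, order(s1$permutation)), img)
  # N = 1 shuffle is the identity
  sid <- shuffle_blocks(partition_blocks(img, 1), 5)
  expect_identical(sid$shuffled_image, img)
  expect_identical(sid$permutation, 1L)
})

test_that("shuffle permutations are uniform over all arrangements", {
  img <- matrix(seq_len(16), 4)
  g <- partition_blocks(img, 2)
  perms <- vapply(seq_len(10000L), function(s) {
    paste(shuffle_blocks(g, s)$permutation, collapse = "")
  }, character(1L))
  counts <- table(perms)
  expect_equal(length(counts), 24L)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("rotation matrices and index mapping follow the row-vector rule", {
  expect_equal(rotation_matrix(1, 4), diag(2))
  expect_equal(rotation_matrix(2, 2), matrix(c(0, 1, -1, 0), 2),
               tolerance = 1e-15)
  s2 <- sqrt(2) / 2
  expect_equal(rotation_matrix(2, 4), matrix(c(s2, s2, -s2, s2), 2),
               tolerance = 1e-15)
  expect_error(rotation_matrix(5, 4), "k")
  expect_equal(map_block_index(c(0, 0), rotation_matrix(3, 7)), c(0, 0))
  # hand multiplication: [1, 0] %*% [[0, -1], [1, 0]] = (0, -1)
  expect_equal(map_block_index(c(1, 0), rotation_matrix(2, 2)), c(0, -1),
               tolerance = 1e-15)
  set.seed(9)
  for (i in 1:100) {
    idx <- runif(2, -3, 3)
    R <- rotation_matrix(sample(1:6, 1), 6)
    expect_lt(abs(sqrt(sum(map_block_index(idx, R)^2)) - sqrt(sum(idx^2))),
              1e-12)
  }
})

test_that("image rotation is exact at 0 and pi and matches index rotation at pi/2", {
  m <- matrix(runif(16), 4)
  expect_identical(rotate_image(m, 0), m)
  expect_identical(rotate_image(m, pi), rot180_idx(m))
  sq <- matrix(runif(49), 7)
  expect_lt(max(abs(rotate_image(sq, pi / 2) - rot90_ccw(sq))), 1e-6)
})

test_that("gray-value matching recovers the inverse permutation", {
  # identity shuffle with distinct means: labels equal index coordinates
  img <- block_constant_image(c(0.1, 0.4, 0.7, 0.9), 2)
  g <- partition_blocks(img, 2)
  expect_equal(assign_shuffled_indices(g, g), g$index_coords)
  # known permutation: recovered labels equal the shuffle-implied truth,
  # and agree with a brute-force search over all 24 one-to-one assignments
  rec <- shuffle_blocks(g, 3)
  gs <- partition_blocks(rec$shuffled_image, 2)
  got <- assign_shuffled_indices(g, gs)
  expect_equal(got, shuffle_truth_labels(g, rec))
  mo <- sapply(1:4, function(t) mean(g$blocks[[t]]))
  ms <- sapply(1:4, function(t) mean(gs$blocks[[t]]))
  all_perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  all_perms <- all_perms[apply(all_perms, 1, function(p) length(unique(p)) == 4), ]
  costs <- apply(all_perms, 1, function(p) sum(abs(mo[p] - ms)))
  best <- all_perms[which.min(costs), ]
  for (s in 1:4) {
    a <- (s - 1) %% 2 + 1; b <- (s - 1) %/% 2 + 1
    oa <- (best[s] - 1) %% 2 + 1; ob <- (best[s] - 1) %/% 2 + 1
    expect_equal(got[a, b, ], g$index_coords[oa, ob, ])
  }
  # exhaustive recovery property at N = 2 and 3
  for (N in 2:3) {
    for (s in 1:5) {
      set.seed(300 + 10 * N + s)
      im <- matrix(runif((4 * N)^2), 4 * N)
      gg <- partition_blocks(im, N)
      rr <- shuffle_blocks(gg, s)
      lab <- assign_shuffled_indices(gg, partition_blocks(rr$shuffled_image, N))
      expect_equal(lab, shuffle_truth_labels(gg, rr))
    }
  }
})

test_that("matching ties break deterministically", {
  img <- block_constant_image(c(0.3, 0.3, 0.6, 0.9), 2)
  g <- partition_blocks(img, 2)
  a <- assign_shuffled_indices(g, g)
  b <- assign_shuffled_indices(g, g)
  expect_identical(a, b)
  # the two equal-mean blocks are assigned in raster order
  expect_equal(a[1, 1, ], g$index_coords[1, 1, ])
  expect_equal(a[2, 1, ], g$index_coords[2, 1, ])
})

test_that("rotation schedules validate their anchor angles", {
  sch <- rotation_schedule()
  expect_equal(sch$K1, 3L)
  expect_equal(sch$K2, 1L)
  expect_equal(sch$angles_original, c(0, pi / 6, pi / 4))
  expect_error(rotation_schedule(c(pi / 6, 0)), "first")
  u <- rotation_schedule(K = 4)
  expect_equal(u$angles_original, (0:3) * pi / 4)
})

test_that("augmented sets carry rotated images and relabelled indices", {
  set.seed(4)
  img <- matrix(runif(24 * 24), 24)
  # trivial schedule: the set is {I} with raw index labels
  triv <- build_augmented_set(img, 1, 2, rotation_schedule(0, numeric(0)),
                              N = 2, seed = 1)
  expect_equal(length(triv$images), 1L)
  expect_identical(triv$images[[1L]], img)
  expect_equal(triv$labels[[1L]], block_index_coords(2))
  # default experimental set {I, I_pi/6, I_pi/4, S}
  aset <- build_augmented_set(img, 2, 3, rotation_schedule(), N = 2, seed = 7)
  expect_equal(length(aset$images), 4L)
  expect_equal(aset$kind, c("original", "original", "original", "shuffled"))
  R <- rotation_matrix(2, 4)  # angle pi/4
  ic <- block_index_coords(2)
  for (a in 1:2) for (b in 1:2) {
    expect_equal(aset$labels[[3L]][a, b, ], map_block_index(ic[a, b, ], R),
                 tolerance = 1e-12)
  }
  expect_equal(aset$onehot, c(0, 1, 0))
  # every label stays within the normalised unit box
  for (v in seq_along(aset$labels)) {
    expect_lte(max(abs(aset$labels[[v]])) / aset$Z, 1 + 1e-12)
  }
  # rotated-shuffled labels compose: S_d labels = S_1 labels x R_d
  sch2 <- rotation_schedule(0, c(0, pi / 4))
  a2 <- build_augmented_set(img, 1, 2, sch2, N = 2, seed = 7)
  for (a in 1:2) for (b in 1:2) {
    expect_equal(a2$labels[[3L]][a, b, ],
                 map_block_index(a2$labels[[2L]][a, b, ], rotation_matrix(2, 4)),
                 tolerance = 1e-12)
  }
})
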