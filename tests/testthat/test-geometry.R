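test_that("coordinate mapping follows the center-anchored similarity model", {
  # identity on equal-size images maps every pixel to itself
  t0 <- similarity_transform()
  px <- as.matrix(expand.grid(0:4, 0:6))
  expect_equal(map_coordinates(t0, c(5, 7), c(5, 7), px),
               px, ignore_attr = TRUE)

  # pure column shift
  t5 <- similarity_transform(tx = 5)
  co <- map_coordinates(t5, c(5, 7), c(5, 7), px)
  expect_equal(co[, 1], px[, 1], ignore_attr = TRUE)
  expect_equal(co[, 2], px[, 2] + 5, ignore_attr = TRUE)

  # 90-degree rotation of a 3x3 template: explicit matrix arithmetic
  t90 <- similarity_transform(theta = 90)
  co90 <- map_coordinates(t90, c(3, 3), c(3, 3), c(0, 0))
  # R(90) (-1,-1) = (1,-1) in (row, col), plus the center (1,1) -> (2, 0)
  expect_equal(as.vector(co90), c(2, 0))

  # the homogeneous matrix agrees with the point mapping
  tt <- similarity_transform(3, -2, 25, 1.1)
  M <- transform_matrix(tt, c(10, 12), c(30, 40))
  pts <- map_coordinates(tt, c(10, 12), c(30, 40), cbind(2, 7))
  v <- M %*% c(7, 2, 1)                  # matrix acts on (col, row)
  expect_equal(as.vector(pts), c(v[2], v[1]))
})

test_that("nearest-neighbour sampling matches a brute-force lookup", {
  set.seed(14)
  mv <- random_index_image(10, 10, 3, seed = 14)
  t1 <- similarity_transform(2, -1, 0, 1)
  out <- sample_moving(mv, t1, c(10, 10))
  # brute-force per-pixel oracle
  brute <- matrix(0L, 10, 10)
  for (r in 0:9) for (c in 0:9) {
    ri <- r - 1; ci <- c + 2                    # ty = -1 shifts rows
    if (ri >= 0 && ri <= 9 && ci >= 0 && ci <= 9)
      brute[r + 1, c + 1] <- mv$labels[ri + 1, ci + 1]
  }
  expect_identical(out$labels, brute)

  # identity is the identity
  expect_identical(sample_moving(mv, similarity_transform(), c(10, 10))$labels,
                   mv$labels)

  # a shift beyond the image gives all background
  far <- sample_moving(mv, similarity_transform(tx = 100), c(10, 10))
  expect_true(all(far$labels == 0L))
})

test_that("compiled sampling and scoring equal the R reference on random transforms", {
  set.seed(15)
  mv <- random_index_image(23, 31, 5, seed = 15)
  fx <- random_index_image(11, 13, 4, seed = 16)
  fn <- make_score_fn(fx, mv, alpha = 0.3)
  for (i in 1:12) {
    tr <- similarity_transform(runif(1, -15, 15), runif(1, -12, 12),
                               runif(1, -180, 180), runif(1, 0.8, 1.2))
    a <- sample_moving(mv, tr, c(11, 13))
    b <- rmireg:::sample_moving_ref(mv, tr, c(11, 13))
    expect_identical(a$labels, b$labels)
    s_batch <- fn(matrix(c(tr$tx, tr$ty, tr$theta, tr$s), 1))
    s_ref <- restricted_mi(joint_histogram(fx, b), alpha = 0.3)
    expect_equal(s_batch, s_ref)
  }
  # integer-translation grouped fast path agrees with the reference too
  par <- cbind(round(runif(40, -15, 15)), round(runif(40, -12, 12)),
               rep(c(0, 10, -33, 121), each = 10), 1)
  got <- fn(par)
  ref <- vapply(seq_len(nrow(par)), function(i) {
    tr <- similarity_transform(par[i, 1], par[i, 2], par[i, 3], par[i, 4])
    restricted_mi(joint_histogram(fx, rmireg:::sample_moving_ref(
      mv, tr, c(11, 13))), alpha = 0.3)
  }, numeric(1))
  expect_equal(got, ref)
})

test_that("score is maximal at self-registration and shift-consistent", {
  a <- random_index_image(14, 14, 4, seed = 21)
  expect_equal(score_transform(a, a, similarity_transform(), alpha = 0),
               joint_histogram(a, a)$HX)

  # composition: pushing the moving content down one row shifts the
  # equivalent sampling position by one row (interior pixels)
  mv <- random_index_image(30, 30, 3, seed = 22)
  shifted <- index_image(rbind(0L, mv$labels[-30, ]), mv$k, mv$modality)
  f <- random_index_image(8, 8, 3, seed = 23)
  s1 <- score_transform(f, mv, similarity_transform(tx = 2, ty = 3))
  s2 <- score_transform(f, shifted, similarity_transform(tx = 2, ty = 4))
  expect_equal(s1, s2)
})

test_that("score is invariant to consistent relabeling of either image", {
  f <- random_index_image(12, 12, 4, seed = 31)
  mv <- random_index_image(20, 20, 5, seed = 32)
  tr <- similarity_transform(1, -2, 15, 1)
  s0 <- score_transform(f, mv, tr)
  perm <- c(0L, sample(5))
  mv_p <- index_image(matrix(perm[mv$labels + 1L], 20, 20), 5, mv$modality)
  expect_equal(score_transform(f, mv_p, tr), s0)
})
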