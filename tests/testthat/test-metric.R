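test_that("joint histogram counts overlapping label pairs", {
  f <- index_image(matrix(c(1, 0, 1, 2), 2, 2), 2)
  mv <- index_image(matrix(c(1, 0, 2, 2), 2, 2), 2)
  jd <- joint_histogram(f, mv)
  expect_equal(jd$m, 4)
  expect_equal(jd$counts["0", "0"], 1)
  expect_equal(jd$counts["1", "1"], 1)
  expect_equal(jd$counts["1", "2"], 1)
  expect_equal(jd$counts["2", "2"], 1)
  expect_equal(sum(jd$counts), 4)

  # identical images concentrate counts on the diagonal: p(x,x) = P(X=x)
  a <- random_index_image(9, 7, 3, seed = 5)
  jd2 <- joint_histogram(a, a)
  expect_equal(diag(jd2$p), jd2$px, ignore_attr = TRUE)
  expect_equal(sum(jd2$counts) - sum(diag(jd2$counts)), 0)

  # random pair equals the brute-force tally
  b <- random_index_image(9, 7, 4, seed = 6)
  jd3 <- joint_histogram(a, b)
  expect_equal(unname(jd3$counts),
               joint_counts_oracle(as.vector(a$labels), as.vector(b$labels),
                                   3, 4))

  expect_error(joint_histogram(a, random_index_image(5, 5, 3, 1)), "shape")
})

test_that("background adjustment reproduces the worked 2x2 example", {
  jd <- joint_dist(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2, byrow = TRUE))
  # alpha = 0 leaves the distribution untouched
  expect_equal(adjust_distribution(jd, 0)$p_alpha, jd$p)
  # alpha = 0.5: hand evaluation of the three defining equations
  ad <- adjust_distribution(jd, 0.5)
  expect_equal(unname(ad$p_alpha),
               matrix(c(0.5, 0.05, 0.05, 0.4), 2, 2, byrow = TRUE))
  # alpha = 1 moves all background-mismatch mass onto (0,0)
  ad1 <- adjust_distribution(jd, 1)
  expect_equal(unname(ad1$p_alpha),
               matrix(c(0.6, 0, 0, 0.4), 2, 2, byrow = TRUE))
  expect_error(adjust_distribution(jd, 1.2), "alpha")
})

test_that("restricted MI matches independent arithmetic on the worked example", {
  jd <- joint_dist(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2, byrow = TRUE))
  # independent oracle: H(X)+H(Y) - cross-entropy, log base 2, by hand
  mi_ref <- 2 - (-(2 * 0.4 * log2(0.4) + 2 * 0.1 * log2(0.1)))
  rmi_ref <- 2 - (-(0.4 * log2(0.5) + 2 * 0.1 * log2(0.05) +
                      0.4 * log2(0.4)))
  expect_equal(standard_mi(jd), mi_ref)
  expect_equal(restricted_mi(jd, 0.5), rmi_ref)
  expect_equal(round(restricted_mi(jd, 0.5), 4), 0.2068)
  expect_equal(round(standard_mi(jd), 4), 0.2781)
  # alpha = 1 zeroes border cells carrying observed mass -> -Inf
  expect_identical(restricted_mi(jd, 1), -Inf)
})

test_that("MI limits: independence gives zero, identity gives H(X)", {
  jd_ind <- joint_dist(matrix(0.25, 2, 2))
  expect_equal(standard_mi(jd_ind), 0)
  expect_equal(restricted_mi(jd_ind, 0), 0)

  a <- random_index_image(12, 12, 4, seed = 8)
  jd_id <- joint_histogram(a, a)
  expect_equal(restricted_mi(jd_id, 0), jd_id$HX)
  # self-registration also peaks at H(X) for alpha > 0 (diagonal support)
  expect_equal(restricted_mi(jd_id, 0.25), jd_id$HX)
})

test_that("adjusted distributions stay normalized and RMI never exceeds MI", {
  set.seed(101)
  for (i in 1:60) {
    kx <- sample(1:6, 1); ky <- sample(1:6, 1)
    cnt <- matrix(rpois((kx + 1) * (ky + 1), 3), kx + 1, ky + 1)
    if (sum(cnt) == 0) cnt[1, 1] <- 1
    jd <- joint_dist(cnt)
    for (alpha in c(0, 0.25, 0.5, 1)) {
      pa <- adjust_distribution(jd, alpha)$p_alpha
      expect_lt(abs(sum(pa) - 1), 1e-12)
      expect_true(all(pa >= 0))
    }
    expect_lt(abs(restricted_mi(jd, 0) - standard_mi(jd)), 1e-12)
    expect_lt(abs(standard_mi(jd) - mi_oracle(jd$p)), 1e-12)
    for (alpha in c(0.1, 0.25, 0.6)) {
      expect_lte(restricted_mi(jd, alpha), restricted_mi(jd, 0) + 1e-12)
    }
  }
})

test_that("RMI is invariant under consistent permutation of nonzero labels", {
  set.seed(33)
  a <- random_index_image(15, 10, 5, seed = 44)
  b <- random_index_image(15, 10, 6, seed = 45)
  jd <- joint_histogram(a, b)
  for (i in 1:5) {
    pa <- c(1, sample(5) + 1)            # permute rows 2..k+1, fix background
    pb <- c(1, sample(6) + 1)
    jd_p <- joint_dist(jd$counts[pa, pb])
    expect_equal(restricted_mi(jd_p, 0.25), restricted_mi(jd, 0.25))
    expect_equal(standard_mi(jd_p), standard_mi(jd))
  }
})

test_that("moving mismatch mass onto the background diagonal rewards RMI", {
  # shifting observation mass from a background-mismatch cell (x != 0, y = 0)
  # onto the background-match cell (0, 0) raises the score in the large
  # majority of tables; it is not an exact monotonicity because the shift
  # also perturbs H(X) and the marginals, so a small slack is allowed
  set.seed(55)
  deltas <- c()
  for (i in 1:60) {
    cnt <- matrix(rpois(12, 4) + 1, 3, 4)
    jd <- joint_dist(cnt)
    cnt2 <- cnt
    cnt2[2, 1] <- cnt2[2, 1] - 1
    cnt2[1, 1] <- cnt2[1, 1] + 1
    jd2 <- joint_dist(cnt2)
    for (alpha in c(0.1, 0.25, 0.5))
      deltas <- c(deltas,
                  restricted_mi(jd2, alpha) - restricted_mi(jd, alpha))
  }
  expect_gte(mean(deltas >= 0), 0.75)
  expect_gte(min(deltas), -0.05)
  expect_gt(mean(deltas), 0)
})
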