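test_that("grid units scale with template geometry", {
  # one rotation unit displaces the corner of the template by about 1 px
  sh <- c(120, 160)
  R <- sqrt(59.5^2 + 79.5^2)
  u <- rotation_grid_unit(sh)
  expect_equal(2 * R * sin(u * pi / 360), 1, tolerance = 1e-9)
  expect_equal(scale_grid_unit(sh), 1 / R)
  # larger templates get finer angular units
  expect_lt(rotation_grid_unit(c(240, 320)), u)
})

test_that("exhaustive search returns the global argmax with lexicographic ties", {
  # hand-written 5x5 score table
  tab <- matrix(0, 5, 5)
  tab[2, 4] <- 3                       # ty = -1, tx = 1 (0-centered grid)
  fn <- function(par) tab[cbind(par[, 2] + 3, par[, 1] + 3)]
  b <- transform_bounds("translation", c(5, 5), c(5, 5),
                        translation_limits = list(tx = c(-2, 2),
                                                  ty = c(-2, 2)))
  res <- exhaustive_search(fn, b)
  expect_equal(res$transform$tx, 1)
  expect_equal(res$transform$ty, -1)
  expect_equal(res$score, 3)
  expect_equal(res$evaluations, 25)

  # one-point bounds return that point
  b1 <- transform_bounds("translation", c(5, 5), c(5, 5),
                         translation_limits = list(tx = c(0, 0),
                                                   ty = c(0, 0)))
  expect_equal(exhaustive_search(fn, b1)$evaluations, 1)

  # constant map: ties broken toward the lexicographically smallest point
  fnc <- function(par) rep(1, nrow(par))
  resc <- exhaustive_search(fnc, b)
  expect_equal(c(resc$transform$tx, resc$transform$ty), c(-2, -2))

  expect_error(exhaustive_search(fn, b, cap = 10), "too large")
})

test_that("sparse search finds the exhaustive argmax on unimodal maps", {
  hits <- 0
  fracs <- c()
  for (seed in 1:25) {
    um <- unimodal_score_map(seed = seed)
    res_s <- sparse_search(um$score_fn, um$bounds, um$r0)
    res_e <- exhaustive_search(um$score_fn, um$bounds)
    expect_lte(res_s$evaluations, res_e$evaluations)
    hits <- hits + (res_s$transform$tx == res_e$transform$tx &&
                      res_s$transform$ty == res_e$transform$ty)
    fracs <- c(fracs, res_s$evaluations / res_e$evaluations)
  }
  expect_gte(hits, 24)                  # >= 96% on this batch
  expect_lt(mean(fracs), 0.15)
})

test_that("sparse search on a constant map stays on the coarse grid", {
  fnc <- function(par) rep(1, nrow(par))
  b <- transform_bounds("translation", c(65, 65), c(65, 65),
                        translation_limits = list(tx = c(-32, 32),
                                                  ty = c(-32, 32)))
  res <- sparse_search(fnc, b, r0 = c(8, 8))
  full <- 65 * 65
  expect_lt(res$evaluations, 0.15 * full)
  # the result is one of the coarse-grid points
  expect_equal(res$transform$tx %% 8, 0)
  expect_equal(res$transform$ty %% 8, 0)
})

test_that("the threshold schedule decays as k0 * delta_k^level", {
  um <- unimodal_score_map(seed = 3)
  res <- sparse_search(um$score_fn, um$bounds, um$r0, k0 = 0.6,
                       delta_k = 0.5)
  expect_equal(res$levels$nu, 0.6 * 0.5^res$levels$level, tolerance = 1e-12)
  # with the canonical initial radius 8 the first four thresholds are
  # 0.6, 0.30, 0.15, 0.075 of the running maximum
  res8 <- sparse_search(um$score_fn, um$bounds, r0 = c(8, 8), k0 = 0.6,
                        delta_k = 0.5)
  expect_equal(res8$levels$nu[1:4], c(0.6, 0.3, 0.15, 0.075),
               tolerance = 1e-12)
})

test_that("sparse search never evaluates a point twice or outside bounds", {
  um <- unimodal_score_map(seed = 9)
  res <- sparse_search(um$score_fn, um$bounds, um$r0, trace = TRUE)
  tr <- res$trace
  expect_equal(nrow(tr), nrow(unique(tr[, c("tx", "ty")])))
  expect_true(all(tr$tx >= -32 & tr$tx <= 32))
  expect_true(all(tr$ty >= -32 & tr$ty <= 32))
  # determinism
  res2 <- sparse_search(um$score_fn, um$bounds, um$r0, trace = TRUE)
  expect_identical(res$trace, res2$trace)
  expect_equal(res$transform, res2$transform)
})

test_that("self-registration radius tracks template structure", {
  # pixel-scale random texture: the score collapses after a 1-px shift
  # (a strict two-color checkerboard would NOT collapse: a 1-px shift swaps
  # the two labels and mutual information is permutation-invariant)
  chk <- random_index_image(40, 40, 3, seed = 77)
  chk$labels[chk$labels == 0L] <- 1L     # no background: pure texture
  b <- transform_bounds("translation", c(40, 40), c(40, 40))
  r0_chk <- estimate_initial_radius(chk, b)
  expect_equal(unname(r0_chk), c(1, 1))

  # one huge uniform blob: wide peak, larger radius than fine texture
  blob <- matrix(0L, 40, 40)
  blob[8:33, 8:33] <- 1L
  r0_blob <- estimate_initial_radius(index_image(blob, 1), b)
  expect_gt(max(r0_blob), max(r0_chk))

  # the estimate never exceeds the basin half-width measured exhaustively
  ph <- small_phantom(seed = 51)
  mask <- background_mask_from_intensity(
    integral_intensity_image(ph$pair$cube))
  fi <- segment_spectral(ph$pair$cube, mask, k = 6, seed = 2)
  bb <- transform_bounds("translation", dim(fi$labels), dim(fi$labels))
  r0 <- estimate_initial_radius(fi, bb, k0 = 0.6)
  fn <- make_score_fn(fi, fi)
  s0 <- fn(matrix(c(0, 0, 0, 1), 1))
  for (j in 1:2) {
    prof <- vapply(1:30, function(d) {
      par <- matrix(c(0, 0, 0, 1), 1); par[j] <- d; fn(par)
    }, numeric(1))
    half_pos <- match(TRUE, prof / s0 < 0.6) - 1
    prof_n <- vapply(1:30, function(d) {
      par <- matrix(c(0, 0, 0, 1), 1); par[j] <- -d; fn(par)
    }, numeric(1))
    half_neg <- match(TRUE, prof_n / s0 < 0.6) - 1
    expect_lte(r0[j], max(half_pos, half_neg, 1))
  }

  # degenerate template errors out
  empty <- index_image(matrix(0L, 20, 20), 2)
  expect_error(estimate_initial_radius(empty, b), "degenerate")
})
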