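test_that("sprays stay inside the image, exclude the center, and repeat under a seed", {
  p <- stress_params(radius = 5, samples = 40, seed = 7)
  set.seed(7)
  s1 <- sample_spray(c(10, 10), p, extent = c(32, 32))
  set.seed(7)
  s2 <- sample_spray(c(10, 10), p, extent = c(32, 32))
  expect_identical(s1, s2)
  expect_true(all(s1[, "x"] >= 0 & s1[, "x"] < 32))
  expect_true(all(s1[, "y"] >= 0 & s1[, "y"] < 32))
  expect_false(any(s1[, "x"] == 10 & s1[, "y"] == 10))

  # radius 1 can only reach the 8-neighborhood
  set.seed(1)
  s8 <- sample_spray(c(10, 10), stress_params(radius = 1, samples = 50),
                     extent = c(32, 32))
  expect_true(all(abs(s8[, "x"] - 10) <= 1 & abs(s8[, "y"] - 10) <= 1))
})

test_that("spray radii are uniform over the disk area", {
  # chi-square on equal-area annuli. Reference bin probabilities come from an
  # independent uniform-disk sampler (rejection in the bounding square) with
  # the same pixel rounding, so the test compares sampling laws rather than
  # penalizing the deterministic rounding shared by both.
  set.seed(1)
  R <- 50
  p <- stress_params(radius = R, samples = 100)
  d <- replicate(100, {
    s <- sample_spray(c(500, 500), p, extent = c(1000, 1000))
    sqrt((s[, "x"] - 500)^2 + (s[, "y"] - 500)^2)
  })
  n_ref <- 1e6
  dx <- runif(2 * n_ref, -R, R); dy <- runif(2 * n_ref, -R, R)
  keep <- dx^2 + dy^2 <= R^2
  d_ref <- sqrt(round(dx[keep])^2 + round(dy[keep])^2)
  breaks <- c(-0.5, R * sqrt(seq(0.1, 1, length.out = 10)))  # equal-area annuli
  counts <- table(cut(c(d), breaks))
  ref_bins <- cut(d_ref, breaks)
  p_ref <- tabulate(ref_bins, nbins = 10) / sum(!is.na(ref_bins))
  expect_gt(stats::chisq.test(counts, p = p_ref, rescale.p = TRUE)$p.value, 0.01)
})

test_that("a constant channel maps to 0.5 everywhere", {
  out <- stress_channel(matrix(0.37, 12, 12), stress_params(seed = 2))
  expect_equal(out, matrix(0.5, 12, 12))
})

test_that("output stays in range, is seed-deterministic, and respects order", {
  set.seed(5)
  ch <- matrix(runif(24 * 24), 24, 24)
  p <- stress_params(radius = 10, samples = 10, iterations = 20, seed = 9)
  a <- stress_channel(ch, p)
  b <- stress_channel(ch, p)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))

  # monotone on a two-valued image: the larger value never maps below the
  # smaller one
  two <- matrix(0.2, 16, 16); two[, 9:16] <- 0.8
  s <- stress_channel(two, stress_params(seed = 4))
  expect_gte(min(s[two == 0.8]), max(s[two == 0.2]))
})

test_that("with exhaustive reach the stretch approaches global min-max", {
  ch <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8, byrow = FALSE)
  ch <- t(ch)  # gradient along columns, 8 pixels per level
  p <- stress_params(radius = 12, samples = 64, iterations = 400, seed = 21)
  s <- stress_channel(ch, p)
  minmax <- (ch - min(ch)) / (max(ch) - min(ch))
  expect_lt(max(abs(s - minmax)), 0.05)
})

test_that("image-level stretch preserves gray under a shared channel seed", {
  img <- array(rep(matrix(runif(64), 8, 8), 3), dim = c(8, 8, 3))
  out <- stress_image(img, stress_params(samples = 10, iterations = 10, seed = 3),
                      share_channel_seed = TRUE)
  expect_equal(out[, , 1], out[, , 2])
  expect_equal(out[, , 2], out[, , 3])
  expect_true(all(out >= 0 & out <= 255))
})

test_that("stretching expands per-channel dynamic range of a low-contrast image", {
  set.seed(8)
  img <- array(runif(16 * 16 * 3, 100, 140), dim = c(16, 16, 3))
  out <- stress_image(img, stress_params(samples = 20, iterations = 50, seed = 13))
  for (k in 1:3)
    expect_gte(diff(range(out[, , k])), diff(range(img[, , k])))
})

test_that("white background of a synthetic scene stays near white", {
  # noiseless scene: with OD noise every background pixel sits slightly below
  # its local spray maximum, which measures the noise, not the stretch
  sc <- small_scene(seed = 19, noise_sigma = 0)
  out <- stress_image(sc$image, stress_params(seed = 5))
  bg <- sc$nuclei_mask == 0
  for (k in 1:3)
    expect_gt(mean(out[, , k][bg] >= 250), 0.99)
})
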