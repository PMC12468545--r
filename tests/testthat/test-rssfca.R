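test_that("Gaussian dissimilarity matches its closed form and direct evaluation", {
  # exponent 0 at the center with identity covariance
  expect_equal(gaussian_neglog(c(1, 2, 3), c(1, 2, 3), diag(3)),
               1.5 * log(2 * pi), tolerance = 1e-12)

  # strictly increasing in the distance from the center
  phis <- vapply(seq(0, 3, by = 0.5), function(d)
    gaussian_neglog(c(d, 0, 0), c(0, 0, 0), diag(3)), numeric(1))
  expect_true(all(diff(phis) > 0))

  # two-path agreement: direct density evaluation then -log
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(3); v <- rnorm(3)
    A <- matrix(rnorm(9), 3); Sig <- crossprod(A) + diag(0.5, 3)
    rho <- exp(-0.5 * t(x - v) %*% solve(Sig) %*% (x - v)) /
      ((2 * pi)^(3 / 2) * sqrt(det(Sig)))
    expect_equal(gaussian_neglog(x, v, Sig), -log(c(rho)), tolerance = 1e-10)
  }
})

test_that("the non-negativity shift preserves column argmins", {
  Phi <- matrix(c(1, 2, 3, 4), 2)
  expect_identical(shift_phi(Phi), Phi)
  Phi2 <- Phi - 3                      # min = -2
  shifted <- shift_phi(Phi2)
  expect_equal(min(shifted), 0)
  expect_equal(shifted, Phi2 + 2)
  expect_identical(apply(shifted, 2, which.min), apply(Phi2, 2, which.min))
})

test_that("membership update solves the simplex-constrained quadratic", {
  # symmetric column splits evenly
  U <- update_memberships(matrix(c(3, 3), 2, 1), gamma = 1)
  expect_equal(c(U), c(0.5, 0.5))

  # large gap excludes the far cluster entirely (self-sparsity)
  U <- update_memberships(matrix(c(0, 10), 2, 1), gamma = 1)
  expect_equal(c(U), c(1, 0))

  # fine-grid brute force at c = 2
  phi <- c(0.4, 1.1); gamma <- 0.7
  grid <- seq(0, 1, by = 1e-5)
  objs <- grid * phi[1] + (1 - grid) * phi[2] + gamma * (grid^2 + (1 - grid)^2)
  u_grid <- grid[which.min(objs)]
  U <- update_memberships(matrix(phi, 2, 1), gamma)
  expect_lt(abs(U[1, 1] - u_grid), 1e-4)

  # support-enumeration oracle on random instances, c up to 5
  set.seed(99)
  for (i in 1:50) {
    c_ <- sample(2:5, 1)
    phi <- runif(c_, 0, 6)
    gamma <- runif(1, 0.2, 4)
    U <- update_memberships(matrix(phi, c_, 1), gamma)
    expect_lt(max(abs(U[, 1] - membership_oracle(phi, gamma))), 1e-9)
    expect_equal(sum(U), 1, tolerance = 1e-12)
  }
})

test_that("center and covariance updates match their formulas", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  U1 <- matrix(1, 1, 20)
  expect_equal(c(update_centers(U1, X)), colMeans(X), tolerance = 1e-12)

  # one-hot memberships give per-cluster plain means
  Uh <- rbind(as.numeric(seq_len(20) <= 10), as.numeric(seq_len(20) > 10))
  ch <- update_centers(Uh, X)
  expect_equal(ch[1, ], colMeans(X[1:10, ]), tolerance = 1e-12)

  # random memberships: direct-formula two-path check
  set.seed(4)
  U <- matrix(runif(40), 2, 20); U <- sweep(U, 2, colSums(U), "/")
  cen <- update_centers(U, X)
  for (i in 1:2)
    expect_equal(cen[i, ], colSums(U[i, ] * X) / sum(U[i, ]), tolerance = 1e-12)

  covs <- update_covariances(U, X, cen, cov_ridge = 1e-6)
  for (i in 1:2) {
    expect_equal(covs[[i]], t(covs[[i]]))
    expect_true(all(eigen(covs[[i]], only.values = TRUE)$values > 0))
  }

  # all data at one point collapses to the ridge
  X0 <- matrix(1, 15, 3)
  cen0 <- update_centers(matrix(1, 1, 15), X0)
  expect_equal(update_covariances(matrix(1, 1, 15), X0, cen0, 1e-6)[[1]],
               diag(1e-6, 3))

  # n-denominator sample covariance for a single full-membership cluster
  cc <- update_covariances(matrix(1, 1, 20), X, matrix(colMeans(X), 1), 0)[[1]]
  expect_equal(cc, cov(X) * 19 / 20, tolerance = 1e-12)
})

test_that("the fit separates Gaussian blobs and decreases its objective", {
  blobs <- gaussian_blobs()
  fit <- rssfca_fit(blobs$X, rssfca_params(seed = 5))
  acc <- max(mean(fit$cluster == blobs$labels),
             mean(fit$cluster == 3 - blobs$labels))
  expect_gte(acc, 0.99)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))

  # memberships are column-stochastic and attain exact zeros
  expect_equal(colSums(fit$U), rep(1, ncol(fit$U)), tolerance = 1e-12)
  expect_true(all(fit$U >= 0 & fit$U <= 1))
  expect_gte(mean(fit$U == 0), 0.5)  # hard assignments: exactly half the entries

  # same seed reproduces the fit exactly
  fit2 <- rssfca_fit(blobs$X, rssfca_params(seed = 5))
  expect_identical(fit$U, fit2$U)
  expect_identical(fit$centers, fit2$centers)
})

test_that("segmentation finds disk nuclei on a white background", {
  sc <- small_scene(seed = 11)
  mask <- segment_image(sc$image, rssfca_params(seed = 3))
  expect_true(all(mask %in% c(0L, 1L)))
  expect_identical(dim(mask), dim(sc$nuclei_mask))
  expect_gte(dice_coefficient(mask, sc$nuclei_mask), 0.95)

  # an all-white image is all background
  white <- array(255, dim = c(24, 24, 3))
  expect_true(all(segment_image(white, rssfca_params(seed = 2)) == 0L))
})
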