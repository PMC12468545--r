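# Forward-model oracle: OD clouds generated from a known basis.
mixture_od <- function(n = 4000, noise = 0, seed = 1,
                       basis = cbind(c(0.650, 0.704, 0.286),
                                     c(0.268, 0.570, 0.776))) {
  basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
  set.seed(seed)
  # sparse per-pixel densities: most pixels dominated by one stain
  which_stain <- sample(1:2, n, replace = TRUE)
  S <- rbind(ifelse(which_stain == 1, runif(n, 0.5, 1.5), runif(n, 0, 0.05)),
             ifelse(which_stain == 2, runif(n, 0.5, 1.5), runif(n, 0, 0.05)))
  od <- basis %*% S
  if (noise > 0) od <- pmax(od + rnorm(length(od), sd = noise), 0)
  list(od = od, basis = basis, S = S)
}

basis_error_deg <- function(est, truth) {
  max(stain_angle(est[, 1], truth[, 1]), stain_angle(est[, 2], truth[, 2]))
}

test_that("SVD angle-percentile estimation recovers a known basis", {
  mix <- mixture_od(noise = 0, seed = 5)
  est <- macenko_stain_vectors(mix$od)
  expect_lt(basis_error_deg(est, mix$basis), 1)

  mixn <- mixture_od(noise = 0.01, seed = 5)
  estn <- macenko_stain_vectors(mixn$od)
  expect_lt(basis_error_deg(estn, mixn$basis), 5)

  # unit-norm, non-negative columns
  expect_equal(colSums(est^2), c(hematoxylin = 1, dab = 1), tolerance = 1e-12)
  expect_true(all(est >= 0))
})

test_that("recovery error grows with OD noise", {
  errs <- vapply(c(0.005, 0.02, 0.08), function(s) {
    mix <- mixture_od(noise = s, seed = 77)
    basis_error_deg(macenko_stain_vectors(mix$od), mix$basis)
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("degenerate OD clouds raise estimation errors", {
  v <- c(0.6, 0.7, 0.39); v <- v / sqrt(sum(v^2))
  rank1 <- v %*% t(runif(500, 0.5, 1.5))
  expect_error(macenko_stain_vectors(rank1), "rank-1")
  expect_error(macenko_stain_vectors(matrix(0.01, 3, 100), beta = 0.15),
               "fewer than 3")
})

test_that("sparse coding matches exact and brute-force solutions", {
  V <- cbind(c(0.650, 0.704, 0.286), c(0.268, 0.570, 0.776))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")

  # exact representation, no penalty
  s <- sparse_code(2 * V[, 1, drop = FALSE], V, lambda = 0)
  expect_equal(c(s), c(2, 0), tolerance = 1e-6)

  # zero pixel codes to zero for any penalty
  expect_equal(c(sparse_code(matrix(0, 3, 1), V, lambda = 0.3)), c(0, 0))

  # penalized solution matches a grid search over [0, 4]^2 at step 1e-3
  od1 <- 2 * V[, 1, drop = FALSE]
  s01 <- sparse_code(od1, V, lambda = 0.1)
  grid <- seq(0, 4, by = 1e-3)
  obj1 <- function(a) 0.5 * sum((od1 - V[, 1] * a)^2) + 0.1 * a
  a_best <- grid[which.min(vapply(grid, obj1, numeric(1)))]
  # at the optimum the second coefficient is inactive
  expect_equal(s01[2, 1], 0)
  expect_lt(abs(s01[1, 1] - a_best), 2e-3)
  expect_lt(s01[1, 1], 2)
})

test_that("sparse coding matches a projected-gradient oracle on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    r <- sample(2:3, 1)
    V <- matrix(runif(3 * r), 3, r)
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    od <- matrix(runif(3, 0, 2), 3, 1)
    lam <- runif(1, 0, 0.3)
    s <- sparse_code(od, V, lam)
    # projected gradient with small steps as an independent route
    u <- rep(0, r); G <- crossprod(V); b <- crossprod(V, od)
    step <- 1 / (2 * max(eigen(G, only.values = TRUE)$values))
    for (i in 1:20000) u <- pmax(u - step * (G %*% u - b + lam), 0)
    expect_lt(max(abs(s - u)), 1e-3)
  }
})

test_that("factorization reconstructs exactly representable data", {
  mix <- mixture_od(noise = 0, seed = 9)
  fit <- nmf_factorize(mix$od, 2, snmf_params(seed = 4))
  rel_err <- sqrt(sum((mix$od - fit$basis %*% fit$density)^2) / sum(mix$od^2))
  expect_lt(rel_err, 1e-3)
  expect_true(all(fit$basis >= 0))
  expect_true(all(fit$density >= 0))
  expect_equal(colSums(fit$basis^2), rep(1, 2), tolerance = 1e-10)
  # alternating minimization never increases the objective
  expect_true(all(diff(fit$objective_trace) <= 1e-10))

  # rank-1 data with r = 1
  v <- c(0.6, 0.7, 0.39); v <- v / sqrt(sum(v^2))
  rank1 <- v %*% t(runif(300, 0.5, 1.5))
  fit1 <- nmf_factorize(rank1, 1, snmf_params(seed = 2, init = "random"))
  expect_lt(sqrt(sum((rank1 - fit1$basis %*% fit1$density)^2) / sum(rank1^2)), 1e-6)
  expect_lt(stain_angle(fit1$basis[, 1], v), 0.1)
})

test_that("zero sparsity reduces the sparse factorization to plain NMF", {
  mix <- mixture_od(noise = 0.01, seed = 14)
  p0 <- snmf_params(lambda_sparsity = 0, seed = 8)
  a <- snmf_factorize(mix$od, 2, p0)
  b <- nmf_factorize(mix$od, 2, p0)
  expect_equal(a$basis, b$basis, tolerance = 1e-10)
  expect_equal(a$density, b$density, tolerance = 1e-10)
})

test_that("the l1 penalty sparsifies density rows and keeps recovery accurate", {
  sc <- small_scene(seed = 23)
  od <- od_flatten(rgb_to_od(sc$image))
  f0 <- snmf_factorize(od, 2, snmf_params(lambda_sparsity = 0, seed = 6))
  f1 <- snmf_factorize(od, 2, snmf_params(lambda_sparsity = 0.1, seed = 6))
  frac_zero <- function(S) mean(S < 1e-10)
  expect_gt(frac_zero(f1$density), frac_zero(f0$density))
  expect_true(all(diff(f1$objective_trace) <= 1e-10))
  est <- order_stains(f1$basis)
  expect_lt(basis_error_deg(est, sc$true_basis), 5)
})

test_that("stain ordering is canonical, idempotent, and robust to rotations", {
  V <- cbind(c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2)),
             c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2)))
  out <- order_stains(V)   # passed in (DAB, hematoxylin) order: must swap
  expect_identical(colnames(out), c("hematoxylin", "dab"))
  expect_equal(out[, "dab"], V[, 1], ignore_attr = TRUE)
  expect_identical(order_stains(out), out)  # idempotent

  # random perturbations up to 20 degrees keep the assignment
  set.seed(55)
  truth <- out
  for (i in 1:100) {
    ang <- runif(2, 0, 20) * pi / 180
    pert <- sapply(1:2, function(j) {
      d <- rnorm(3); d <- d - sum(d * truth[, j]) * truth[, j]
      d <- d / sqrt(sum(d^2))
      v <- cos(ang[j]) * truth[, j] + sin(ang[j]) * d
      v <- pmax(v, 0); v / sqrt(sum(v^2))
    })
    got <- order_stains(pert[, sample(1:2)])
    expect_lt(stain_angle(got[, "hematoxylin"], truth[, "hematoxylin"]), 25)
    expect_lt(stain_angle(got[, "dab"], truth[, "dab"]), 25)
  }
})
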