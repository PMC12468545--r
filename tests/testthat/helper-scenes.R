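# Shared fixtures, all generated in code under fixed seeds.

# Small scene for fast oracle tests; geometry scaled down from the defaults,
# stain densities and noise kept at the default study conditions.
small_scene <- function(seed = 11, noise_sigma = 0.01, ...) {
  make_scene(synth_config(height = 96, width = 96, n_nuclei = 8,
                          radius_range = c(6, 10), noise_sigma = noise_sigma,
                          seed = seed, ...))
}

# Scene satisfying the classifier conditions: both stains present in every
# nucleus with a positive:negative peak-density ratio of at least 3.2, OD
# noise at the 0.02 ceiling.
classifier_scene <- function(seed) {
  make_scene(synth_config(height = 128, width = 128, n_nuclei = 14,
                          radius_range = c(6, 10),
                          cross_density_range = c(0.05, 0.25),
                          noise_sigma = 0.02, seed = seed))
}

# Exhaustive oracle for the sparse membership update: enumerate every
# non-empty support set, solve the equality-constrained quadratic on it in
# closed form, keep feasible candidates, return the objective minimizer.
# Independent of the sorting-based implementation path.
membership_oracle <- function(phi, gamma) {
  c_ <- length(phi)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^c_ - 1)) {
    A <- which(bitwAnd(mask, 2^(seq_len(c_) - 1)) > 0)
    theta <- (2 * gamma + sum(phi[A])) / length(A)
    u <- numeric(c_)
    u[A] <- (theta - phi[A]) / (2 * gamma)
    if (any(u[A] < -1e-12)) next
    obj <- sum(u * phi + gamma * u^2)
    if (obj < best_obj) { best_obj <- obj; best <- u }
  }
  pmax(best, 0)
}

# Two separated isotropic Gaussian blobs with labels.
gaussian_blobs <- function(n_per = 1000, d = 3, sep = 4, sd = 0.5, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, sd), ncol = d),
             matrix(rnorm(n_per * d, sep, sd), ncol = d))
  list(X = X, labels = rep(1:2, each = n_per))
}

random_image <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

dice_coefficient <- function(a, b) {
  2 * sum(a == 1 & b == 1) / (sum(a == 1) + sum(b == 1))
}
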