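#' Parameters for the quaternion structural similarity metric
#'
#' @param window sliding-window side length in pixels (>= 2, default 8).
#' @param stride window step (default 1).
#' @param epsilon stabilizer added to the scalar part of each numerator and
#'   to each denominator, defining the constant-window limit (two identical
#'   flat windows score 1); default 1e-12.
#' @return A list of class `qssim_params`.
#' @export
qssim_params <- function(window = 8, stride = 1, epsilon = 1e-12) {
  if (window < 2) stop("`window` must be >= 2")
  if (stride < 1) stop("`stride` must be >= 1")
  if (epsilon <= 0) stop("`epsilon` must be > 0")
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 epsilon = epsilon), class = "qssim_params")
}

#' Represent an RGB image as a pure-quaternion field
#'
#' Each pixel (r, g, b) on the \[0, 255\] scale maps to the pure quaternion
#' `0 + (r/255) i + (g/255) j + (b/255) k`. The scalar plane is identically
#' zero; the mapping is exactly invertible.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @return H x W x 4 array; plane 1 is the (zero) scalar part.
#' @export
to_quaternion <- function(image) {
  stopifnot_image(image)
  d <- dim(image)
  q <- array(0, dim = c(d[1], d[2], 4L))
  q[, , 2:4] <- image / 255
  q
}

#' @rdname to_quaternion
#' @param q H x W x 4 pure-quaternion array.
#' @export
from_quaternion <- function(q) {
  if (max(abs(q[, , 1])) > 0) stop("`q` must be a pure quaternion field")
  q[, , 2:4, drop = TRUE] * 255
}

# Summed-area-table box means at all window positions for one plane.
box_means <- function(m, w, stride) {
  H <- nrow(m); W <- ncol(m)
  sat <- matrix(0, H + 1, W + 1)
  sat[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  ri <- seq(1, H - w + 1, by = stride)
  ci <- seq(1, W - w + 1, by = stride)
  (sat[ri + w, ci + w, drop = FALSE] - sat[ri, ci + w, drop = FALSE] -
     sat[ri + w, ci, drop = FALSE] + sat[ri, ci, drop = FALSE]) / (w * w)
}

#' Quaternion structural similarity between two color images
#'
#' Treats each pixel as a pure quaternion and compares the two images window
#' by window. In each window, with quaternion means `mu_ref`, `mu_deg`,
#' variances `sigma^2` (mean squared modulus of the centered quaternions) and
#' quaternion cross-covariance
#' `sigma_rd = mean((q_ref - mu_ref) * conj(q_deg - mu_deg))`, the window
#' score is the modulus of the product of a luminance term
#' `2 mu_ref conj(mu_deg) / (|mu_ref|^2 + |mu_deg|^2)` and a structural term
#' `2 sigma_rd / (sigma_ref^2 + sigma_deg^2)`; both terms are epsilon-
#' stabilized so that two identical constant windows score exactly 1. The
#' image score is the mean of the window scores, clipped to \[0, 1\]. The
#' score equals 1 exactly when the images are identical, and its modulus is
#' symmetric in the two arguments.
#'
#' @param ref,deg H x W x 3 arrays in \[0, 255\] with identical dimensions.
#' @param params a [qssim_params()] object.
#' @param global if `TRUE`, evaluate the formula once over the whole image
#'   instead of windowing.
#' @return Scalar score in \[0, 1\].
#' @export
qssim_score <- function(ref, deg, params = qssim_params(), global = FALSE) {
  stopifnot_image(ref, "ref"); stopifnot_image(deg, "deg")
  if (!identical(dim(ref), dim(deg))) stop("`ref` and `deg` dimensions differ")
  eps <- params$epsilon
  w <- if (global) min(dim(ref)[1:2]) else params$window
  if (global) {
    # one "window" covering the whole image: plain means
    bm <- function(m) mean(m)
  } else {
    if (any(dim(ref)[1:2] < w)) stop("image smaller than the QSSIM window")
    bm <- function(m) box_means(m, w, params$stride)
  }
  A <- ref / 255; B <- deg / 255
  mu_a <- lapply(1:3, function(k) bm(A[, , k]))
  mu_b <- lapply(1:3, function(k) bm(B[, , k]))
  e_a2 <- lapply(1:3, function(k) bm(A[, , k] * A[, , k]))
  e_b2 <- lapply(1:3, function(k) bm(B[, , k] * B[, , k]))
  cross <- lapply(1:3, function(i) lapply(1:3, function(j) bm(A[, , i] * B[, , j])))
  cov_ij <- function(i, j) cross[[i]][[j]] - mu_a[[i]] * mu_b[[j]]

  mu_a2 <- mu_a[[1]]^2 + mu_a[[2]]^2 + mu_a[[3]]^2
  mu_b2 <- mu_b[[1]]^2 + mu_b[[2]]^2 + mu_b[[3]]^2
  var_a <- (e_a2[[1]] - mu_a[[1]]^2) + (e_a2[[2]] - mu_a[[2]]^2) +
    (e_a2[[3]] - mu_a[[3]]^2)
  var_b <- (e_b2[[1]] - mu_b[[1]]^2) + (e_b2[[2]] - mu_b[[2]]^2) +
    (e_b2[[3]] - mu_b[[3]]^2)
  var_a <- pmax(var_a, 0); var_b <- pmax(var_b, 0)

  # luminance term: 2 mu_ref conj(mu_deg); for pure quaternions (0, a)(0, -b)
  # the Hamilton product is (a.b, -a x b)
  dot_mu <- mu_a[[1]] * mu_b[[1]] + mu_a[[2]] * mu_b[[2]] + mu_a[[3]] * mu_b[[3]]
  cr1 <- mu_a[[2]] * mu_b[[3]] - mu_a[[3]] * mu_b[[2]]
  cr2 <- mu_a[[3]] * mu_b[[1]] - mu_a[[1]] * mu_b[[3]]
  cr3 <- mu_a[[1]] * mu_b[[2]] - mu_a[[2]] * mu_b[[1]]
  lum <- sqrt((2 * dot_mu + eps)^2 + 4 * (cr1^2 + cr2^2 + cr3^2)) /
    (mu_a2 + mu_b2 + eps)

  # structural term: quaternion cross-covariance (a - mu_a) conj(b - mu_b)
  s0 <- cov_ij(1, 1) + cov_ij(2, 2) + cov_ij(3, 3)
  s1 <- -(cov_ij(2, 3) - cov_ij(3, 2))
  s2 <- -(cov_ij(3, 1) - cov_ij(1, 3))
  s3 <- -(cov_ij(1, 2) - cov_ij(2, 1))
  # Cauchy-Schwarz cap |sigma_rd| <= sqrt(var_a * var_b): mathematically a
  # no-op, but it suppresses summed-area-table cancellation noise in flat
  # windows (where the true variances and covariance are all zero)
  smod <- sqrt(s0^2 + s1^2 + s2^2 + s3^2)
  cap <- pmin(1, sqrt(var_a * var_b) / pmax(smod, .Machine$double.xmin))
  s0 <- s0 * cap; s1 <- s1 * cap; s2 <- s2 * cap; s3 <- s3 * cap
  str_ <- sqrt((2 * s0 + eps)^2 + 4 * (s1^2 + s2^2 + s3^2)) /
    (var_a + var_b + eps)

  mean(pmin(pmax(lum * str_, 0), 1))
}
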