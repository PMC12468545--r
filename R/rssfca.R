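#' Parameters for robust self-sparse fuzzy clustering
#'
#' @param c number of clusters (>= 2; default 2, background vs nuclei).
#' @param gamma quadratic membership regularizer (> 0). Small gamma relative
#'   to the spread of the Gaussian dissimilarities yields exactly-sparse
#'   memberships; default 3 on \[0, 1\]-scaled RGB features.
#' @param eta convergence threshold on the objective change (default 1e-5).
#' @param T maximum iterations (default 100).
#' @param seed RNG seed for the fuzzy c-means initialization.
#' @param cov_ridge diagonal loading added to every covariance update to keep
#'   it positive-definite (default 1e-6).
#' @return A list of class `rssfca_params`.
#' @export
rssfca_params <- function(c = 2, gamma = 3, eta = 1e-5, T = 100, seed = NULL,
                          cov_ridge = 1e-6) {
  if (c < 2) stop("`c` must be >= 2")
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (eta <= 0) stop("`eta` must be > 0")
  if (T < 1) stop("`T` must be >= 1")
  structure(list(c = as.integer(c), gamma = gamma, eta = eta,
                 T = as.integer(T), seed = seed, cov_ridge = cov_ridge),
            class = "rssfca_params")
}

#' Negative log Gaussian density
#'
#' The dissimilarity used by the clustering objective:
#' `Phi = 0.5 * (x - v)' Sigma^-1 (x - v) + (D/2) log(2 pi) + 0.5 * log|Sigma|`,
#' i.e. minus the log of the multivariate normal density. Strictly increasing
#' in the Mahalanobis distance of `x` from the center.
#'
#' @param x numeric feature vector (length D).
#' @param center cluster center (length D).
#' @param covariance D x D symmetric positive-definite matrix.
#' @return Scalar Phi (can be negative when the density exceeds 1).
#' @export
gaussian_neglog <- function(x, center, covariance) {
  d <- x - center
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance is not positive-definite"))
  z <- backsolve(ch, d, transpose = TRUE)
  0.5 * sum(z^2) + 0.5 * length(x) * log(2 * pi) + sum(log(diag(ch)))
}

# c x n matrix of Phi values for all clusters and points (X is n x D).
phi_matrix <- function(X, centers, covariances) {
  c_ <- nrow(centers); n <- nrow(X); D <- ncol(X)
  Phi <- matrix(0, c_, n)
  for (i in seq_len(c_)) {
    ch <- tryCatch(chol(covariances[[i]]),
                   error = function(e) stop("covariance is not positive-definite"))
    d <- t(X) - centers[i, ]
    z <- backsolve(ch, d, transpose = TRUE)
    Phi[i, ] <- 0.5 * colSums(z^2) + 0.5 * D * log(2 * pi) + sum(log(diag(ch)))
  }
  Phi
}

#' Shift dissimilarities to be non-negative
#'
#' Tight covariances make the Gaussian density exceed 1 and Phi go negative,
#' which corrupts the membership weighting; when the global minimum of the
#' matrix is negative the whole matrix is shifted up by it. A uniform shift
#' never changes any column's argmin.
#'
#' @param Phi c x n matrix of dissimilarities.
#' @return Matrix with minimum >= 0.
#' @export
shift_phi <- function(Phi) {
  if (!all(is.finite(Phi))) stop("`Phi` must be finite")
  m <- min(Phi)
  if (m < 0) Phi - m else Phi
}

#' Sparse membership update
#'
#' Per pixel j, minimizes `sum_i(u_i * Phi'_ij + gamma * u_i^2)` over the
#' probability simplex. Completing the square shows this is the Euclidean
#' projection of `-Phi'_j / (2 gamma)` onto the simplex, solved in closed
#' form by the sorting algorithm; the KKT solution
#' `u_i = max(0, (theta_j - Phi'_ij) / (2 gamma))` attains exact zeros, which
#' is the self-sparsity property. Vectorized over all pixels.
#'
#' @param PhiPrime c x n non-negative dissimilarity matrix.
#' @param gamma positive regularizer.
#' @return c x n membership matrix; every column sums to 1.
#' @export
update_memberships <- function(PhiPrime, gamma) {
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (min(PhiPrime) < 0) stop("`PhiPrime` must be non-negative (see shift_phi)")
  c_ <- nrow(PhiPrime); n <- ncol(PhiPrime)
  Z <- -PhiPrime / (2 * gamma)
  if (c_ == 2L) {
    u1 <- pmin(pmax((Z[1, ] - Z[2, ] + 1) / 2, 0), 1)
    return(rbind(u1, 1 - u1, deparse.level = 0))
  }
  Zs <- apply(Z, 2, sort, decreasing = TRUE)          # c x n sorted columns
  if (is.null(dim(Zs))) Zs <- matrix(Zs, nrow = c_)
  csum <- apply(Zs, 2, cumsum)
  if (is.null(dim(csum))) csum <- matrix(csum, nrow = c_)
  ks <- matrix(seq_len(c_), c_, n)
  feas <- Zs - (csum - 1) / ks > 0
  k <- colSums(feas)                 # feasibility is prefix-monotone in k
  theta <- (csum[cbind(k, seq_len(n))] - 1) / k
  U <- pmax(Z - rep(theta, each = c_), 0)
  U
}

#' Membership-weighted cluster centers
#'
#' `v_i = sum_j u_ij x_j / sum_j u_ij`. A cluster whose total membership is
#' zero is reseeded from a random data point (with a warning).
#'
#' @param U c x n membership matrix.
#' @param X n x D data matrix.
#' @return c x D matrix of centers.
#' @export
update_centers <- function(U, X) {
  w <- rowSums(U)
  centers <- matrix(0, nrow(U), ncol(X))
  for (i in seq_len(nrow(U))) {
    if (w[i] <= 0) {
      warning(sprintf("cluster %d lost all membership; reseeding its center", i))
      centers[i, ] <- X[sample(nrow(X), 1), ]
    } else {
      centers[i, ] <- colSums(U[i, ] * X) / w[i]
    }
  }
  centers
}

#' Membership-weighted cluster covariances
#'
#' `Sigma_i = sum_j u_ij (x_j - v_i)(x_j - v_i)' / sum_j u_ij`, plus
#' `cov_ridge * I` diagonal loading so the matrix stays positive-definite
#' even when a cluster collapses onto a point or a plane.
#'
#' @inheritParams update_centers
#' @param centers c x D matrix from [update_centers()].
#' @param cov_ridge non-negative diagonal loading.
#' @return List of c D x D covariance matrices.
#' @export
update_covariances <- function(U, X, centers, cov_ridge = 1e-6) {
  D <- ncol(X)
  lapply(seq_len(nrow(U)), function(i) {
    w <- U[i, ]; tw <- sum(w)
    if (tw <= 0) {
      warning(sprintf("cluster %d has zero membership; using ridge covariance", i))
      return(diag(cov_ridge, D))
    }
    d <- sweep(X, 2, centers[i, ])
    (crossprod(d * w, d)) / tw + diag(cov_ridge, D)
  })
}

# Standard fuzzy c-means (fuzzifier m = 2) used only for initialization.
fcm_init <- function(X, c_, iters = 20) {
  n <- nrow(X)
  centers <- X[sample(n, c_), , drop = FALSE]
  U <- NULL
  for (it in seq_len(iters)) {
    d2 <- sapply(seq_len(c_), function(i) colSums((t(X) - centers[i, ])^2))
    d2 <- t(pmax(d2, 1e-12))                       # c x n
    inv <- 1 / d2
    U <- inv / rep(colSums(inv), each = c_)
    centers <- (U^2 %*% X) / rowSums(U^2)
  }
  list(U = U, centers = centers)
}

#' Fit a robust self-sparse fuzzy clustering model
#'
#' Minimizes `sum_ij u_ij Phi'(x_j | v_i, Sigma_i) + gamma * sum_ij u_ij^2`
#' over memberships on the simplex, Gaussian centers and covariances, by
#' alternating the closed-form updates [update_memberships()],
#' [update_centers()] and [update_covariances()]. Memberships and centers are
#' initialized with 20 iterations of standard fuzzy c-means (fuzzifier 2,
#' seeded); covariances from the weighted covariance of that initialization
#' plus diagonal loading. Iteration stops when the objective changes by at
#' most `eta` or after `T` iterations.
#'
#' @param X n x D data matrix (one row per pixel/observation).
#' @param params an [rssfca_params()] object.
#' @return Object of class `rssfca`: memberships `U` (c x n), `centers`,
#'   `covariances`, hard labels `cluster`, `objective`, `objective_trace`,
#'   `iterations`, `converged`.
#' @export
rssfca_fit <- function(X, params = rssfca_params()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  c_ <- params$c
  if (nrow(X) <= c_) stop("need more data points than clusters")
  with_seed(params$seed, {
    ini <- fcm_init(X, c_)
    centers <- ini$centers
    covs <- update_covariances(ini$U, X, centers, params$cov_ridge)
    U <- ini$U
    obj <- Inf
    trace <- numeric(0)
    converged <- FALSE
    for (t in seq_len(params$T)) {
      PhiP <- shift_phi(phi_matrix(X, centers, covs))
      U <- update_memberships(PhiP, params$gamma)
      centers <- update_centers(U, X)
      covs <- update_covariances(U, X, centers, params$cov_ridge)
      new_obj <- sum(U * PhiP) + params$gamma * sum(U^2)
      trace <- c(trace, new_obj)
      if (is.finite(obj) && abs(new_obj - obj) <= params$eta) {
        obj <- new_obj; converged <- TRUE; break
      }
      obj <- new_obj
    }
    structure(list(U = U, centers = centers, covariances = covs,
                   cluster = apply(U, 2, which.max), objective = obj,
                   objective_trace = trace, iterations = length(trace),
                   converged = converged, params = params),
              class = "rssfca")
  })
}

#' @export
print.rssfca <- function(x, ...) {
  cat("Robust self-sparse fuzzy clustering\n")
  cat(sprintf("  clusters: %d  points: %d  dims: %d\n",
              nrow(x$centers), ncol(x$U), ncol(x$centers)))
  cat(sprintf("  iterations: %d (%s)  objective: %.6g\n", x$iterations,
              if (x$converged) "converged" else "max iterations", x$objective))
  cat(sprintf("  zero memberships: %.1f%%\n", 100 * mean(x$U == 0)))
  invisible(x)
}

#' Segment an IHC image into nuclei and background
#'
#' Clusters the per-pixel RGB features (scaled to \[0, 1\]) with
#' [rssfca_fit()], assigns each pixel to its maximum-membership cluster, and
#' calls the cluster whose center has the highest luminance "background"
#' (IHC backgrounds are near-white); every other cluster is "nuclei".
#' Connected nuclei components smaller than `min_area_fraction` of the image
#' are reassigned to background — a simple area filter standing in for
#' connected-component post-processing.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param params an [rssfca_params()] object.
#' @param min_area_fraction components below this fraction of total pixels
#'   are dropped from the nuclei mask (default 1e-4).
#' @return Integer H x W matrix: 0 = background, 1 = nuclei, with attribute
#'   `fit` holding the `rssfca` object.
#' @export
segment_image <- function(image, params = rssfca_params(),
                          min_area_fraction = 1e-4) {
  stopifnot_image(image)
  d <- dim(image)
  X <- matrix(image, ncol = 3L) / 255
  fit <- rssfca_fit(X, params)
  lum <- as.numeric(fit$centers %*% LUMA_WEIGHTS)
  background <- which.max(lum)
  nuclei <- matrix(as.integer(fit$cluster != background), d[1], d[2])
  if (any(nuclei == 1L)) {
    lab <- EBImage::bwlabel(nuclei)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_area_fraction * length(nuclei))
    if (length(small)) nuclei[lab %in% small] <- 0L
  }
  attr(nuclei, "fit") <- fit
  nuclei
}
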