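# Canonical OD-space unit directions for the two IHC stains (Ruifrok-style
# constants): hematoxylin counterstains immunonegative nuclei blue, DAB marks
# immunopositive nuclei brown. Used only to give estimated bases a fixed,
# reproducible column order.
CANONICAL_HEMATOXYLIN <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
CANONICAL_DAB <- c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2))

#' Order stain-basis columns hematoxylin-first
#'
#' Estimated stain bases come out of factorizations in arbitrary column
#' order. This assigns each column to the canonical hematoxylin or DAB OD
#' direction by angular proximity and returns the basis with the
#' hematoxylin-like (immunonegative) column first and the DAB-like
#' (immunopositive) column second. If both columns are closer to the same
#' canonical direction the tie is broken by blue-channel OD weight
#' (hematoxylin absorbs little blue light) with a warning. A third (residual)
#' column, if present, stays last.
#'
#' @param basis 3 x r matrix of unit-norm stain OD vectors, r in \{2, 3\}.
#' @return The basis with ordered columns and `colnames`
#'   `c("hematoxylin", "dab")` (plus `"residual"`).
#' @export
order_stains <- function(basis) {
  r <- ncol(basis)
  if (!r %in% c(2L, 3L)) stop("`basis` must have 2 or 3 columns")
  a_h <- c(stain_angle(basis[, 1], CANONICAL_HEMATOXYLIN),
           stain_angle(basis[, 2], CANONICAL_HEMATOXYLIN))
  a_d <- c(stain_angle(basis[, 1], CANONICAL_DAB),
           stain_angle(basis[, 2], CANONICAL_DAB))
  assign1 <- which.min(a_h)          # column acting as hematoxylin
  assign2 <- which.min(a_d)          # column acting as DAB
  if (assign1 == assign2) {
    warning("ambiguous stain assignment; ordering by blue-channel OD weight")
    assign1 <- which.min(basis[3, 1:2])
    assign2 <- setdiff(1:2, assign1)
  }
  idx <- c(assign1, assign2, if (r == 3L) 3L)
  out <- basis[, idx, drop = FALSE]
  colnames(out) <- c("hematoxylin", "dab", if (r == 3L) "residual")
  out
}

#' Automatic stain-vector estimation (Macenko method)
#'
#' Estimates the two stain OD color vectors of an image from the geometry of
#' its OD point cloud: low-OD (background) pixels are discarded, the remaining
#' tuples are projected onto their rank-2 singular plane, normalized to unit
#' length, and the directions at robust extreme angles (the `alpha` and
#' `100 - alpha` percentiles of the angle distribution) are mapped back to OD
#' space as the stain vectors.
#'
#' @param od 3 x n matrix of per-pixel optical densities (see
#'   [od_flatten()]).
#' @param beta OD threshold: pixels whose maximum-channel OD is below `beta`
#'   are dropped before the SVD (default 0.15). Use `NA` or `Inf` to skip the
#'   filtering entirely (the automatic-color-deconvolution classifier does
#'   this).
#' @param alpha robust-extreme percentile in (0, 50); default 1 uses the
#'   1st/99th angle percentiles.
#' @return 3 x 2 matrix of unit-norm, non-negative stain vectors ordered by
#'   [order_stains()].
#' @export
macenko_stain_vectors <- function(od, beta = 0.15, alpha = 1) {
  if (!is.matrix(od) || nrow(od) != 3L) stop("`od` must be a 3 x n matrix")
  if (!all(is.finite(od)) || min(od) < -1e-9) stop("`od` must be finite and >= 0")
  if (alpha <= 0 || alpha >= 50) stop("`alpha` must be in (0, 50)")
  keep <- if (is.null(beta) || is.na(beta) || !is.finite(beta)) {
    rep(TRUE, ncol(od))
  } else {
    apply(od, 2, max) >= beta
  }
  x <- od[, keep, drop = FALSE]
  if (ncol(x) < 3L)
    stop("stain estimation failed: fewer than 3 pixels survive OD filtering")
  sv <- svd(x, nu = 3, nv = 0)
  if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] < 1e-6)
    stop("stain estimation failed: OD cloud is (near) rank-1, a single stain")
  u <- sv$u[, 1:2, drop = FALSE]
  # reproducible sign convention: mean projected coordinate non-negative
  proj <- crossprod(u, x)                      # 2 x n'
  for (k in 1:2) if (mean(proj[k, ]) < 0) { u[, k] <- -u[, k]; proj[k, ] <- -proj[k, ] }
  nrm <- sqrt(colSums(proj^2))
  ok <- nrm > 1e-12
  proj <- proj[, ok, drop = FALSE] / rep(nrm[ok], each = 2)
  ang <- atan2(proj[2, ], proj[1, ])
  ext <- stats::quantile(ang, c(alpha, 100 - alpha) / 100, names = FALSE)
  v <- cbind(u %*% c(cos(ext[1]), sin(ext[1])),
             u %*% c(cos(ext[2]), sin(ext[2])))
  v[v < 0] <- 0
  nv <- sqrt(colSums(v^2))
  if (any(nv < 1e-8))
    stop("stain estimation failed: degenerate (non-positive) extreme direction")
  order_stains(sweep(v, 2, nv, "/"))
}

#' Sparse coding of stain densities against a fixed basis
#'
#' Per pixel j, solves the non-negative lasso
#' `min_s 0.5 * ||od_j - V s||^2 + lambda * sum(s)` subject to `s >= 0` by
#' cyclic coordinate descent (closed-form coordinate updates; the problem is
#' convex and separable across pixels, so the solver is vectorized over all
#' pixels at once). With `lambda = 0` this is plain non-negative least
#' squares.
#'
#' @param od 3 x n OD matrix.
#' @param basis 3 x r matrix with unit-norm columns.
#' @param lambda non-negative l1 penalty weight (default 0.1).
#' @param max_iters,tol coordinate-descent sweep limit and convergence
#'   threshold on the largest coefficient change.
#' @param S_init optional r x n warm start (defaults to a thresholded
#'   correlation start); coordinate descent is monotone from any start.
#' @return r x n non-negative density matrix.
#' @export
sparse_code <- function(od, basis, lambda = 0.1, max_iters = 200, tol = 1e-8,
                        S_init = NULL) {
  if (!is.matrix(od) || nrow(od) != 3L) stop("`od` must be a 3 x n matrix")
  r <- ncol(basis)
  if (lambda < 0) stop("`lambda` must be >= 0")
  cn <- sqrt(colSums(basis^2))
  if (any(abs(cn - 1) > 1e-6)) stop("`basis` columns must be unit-norm")
  G <- crossprod(basis)            # r x r Gram
  B <- crossprod(basis, od)        # r x n
  S <- if (is.null(S_init)) pmax(B - lambda, 0) else S_init
  for (it in seq_len(max_iters)) {
    delta <- 0
    for (k in seq_len(r)) {
      cross <- if (r > 1) G[k, -k, drop = FALSE] %*% S[-k, , drop = FALSE] else 0
      new_k <- pmax((B[k, ] - cross - lambda) / G[k, k], 0)
      delta <- max(delta, max(abs(new_k - S[k, ])))
      S[k, ] <- new_k
    }
    if (delta < tol) break
  }
  dimnames(S) <- list(colnames(basis), NULL)
  S
}

#' Parameters for (sparse) non-negative matrix factorization
#'
#' @param lambda_sparsity l1 weight on density rows (default 0.1; 0 gives
#'   plain NMF).
#' @param max_iters maximum outer alternating iterations.
#' @param tol relative objective-change convergence threshold.
#' @param seed RNG seed for the initialization.
#' @param init `"macenko"` (default; falls back to random on failure) or
#'   `"random"` (seeded data columns).
#' @return A list of class `snmf_params`.
#' @export
snmf_params <- function(lambda_sparsity = 0.1, max_iters = 200, tol = 1e-6,
                        seed = NULL, init = c("macenko", "random")) {
  if (lambda_sparsity < 0) stop("`lambda_sparsity` must be >= 0")
  if (tol <= 0) stop("`tol` must be > 0")
  structure(list(lambda_sparsity = lambda_sparsity,
                 max_iters = as.integer(max_iters), tol = tol, seed = seed,
                 init = match.arg(init)),
            class = "snmf_params")
}

# Exact minimizer of the factorization objective over one dictionary column
# restricted to the non-negative unit sphere: u = g+ / ||g+||.
update_basis_columns <- function(V, A, B) {
  flagged <- FALSE
  for (k in seq_len(ncol(V))) {
    g <- B[, k] - V %*% A[, k] + V[, k] * A[k, k]
    g <- pmax(as.numeric(g), 0)
    ng <- sqrt(sum(g^2))
    if (ng > 1e-12) V[, k] <- g / ng else flagged <- TRUE
  }
  attr(V, "stalled_column") <- flagged
  V
}

snmf_objective <- function(od, V, S, lambda) {
  0.5 * sum((od - V %*% S)^2) + lambda * sum(S)
}

snmf_engine <- function(od, r, lambda, params) {
  n <- ncol(od)
  if (r < 1) stop("`r` must be >= 1")
  if (min(od) < -1e-9) stop("`od` must be non-negative")
  init_V <- NULL
  if (params$init == "macenko" && r == 2L)
    init_V <- tryCatch(macenko_stain_vectors(od), error = function(e) NULL)
  if (is.null(init_V)) {
    init_V <- with_seed(params$seed, {
      nrm <- sqrt(colSums(od^2))
      cand <- which(nrm > stats::quantile(nrm, 0.5))
      if (length(cand) < r) cand <- seq_len(n)
      idx <- sample(cand, r)
      sweep(od[, idx, drop = FALSE] + 1e-3, 2,
            sqrt(colSums((od[, idx, drop = FALSE] + 1e-3)^2)), "/")
    })
  }
  V <- init_V
  S <- sparse_code(od, V, lambda)
  obj <- snmf_objective(od, V, S, lambda)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    A <- tcrossprod(S)                 # r x r
    B <- tcrossprod(od, S)             # 3 x r
    V <- update_basis_columns(V, A, B)
    S <- sparse_code(od, V, lambda, S_init = S)
    new_obj <- snmf_objective(od, V, S, lambda)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= params$tol * max(obj, .Machine$double.eps)) {
      obj <- new_obj; converged <- TRUE; break
    }
    obj <- new_obj
  }
  dimnames(V) <- NULL
  list(basis = V, density = S, objective = obj, objective_trace = trace,
       iterations = length(trace) - 1L, converged = converged,
       lambda = lambda)
}

#' Non-negative matrix factorization of an OD image
#'
#' Factorizes `od ~ V S` with `V, S >= 0` by alternating exact block updates:
#' densities by non-negative least squares ([sparse_code()] with zero
#' penalty), dictionary columns by closed-form minimization over the
#' non-negative unit sphere. The objective `0.5 * ||od - V S||_F^2` is
#' non-increasing across iterations; basis columns are unit-norm throughout
#' (the scale lives in S).
#'
#' @param od 3 x n non-negative OD matrix.
#' @param r number of stains (1-3).
#' @param params an [snmf_params()] object; its `lambda_sparsity` is ignored
#'   (forced to 0).
#' @return List with `basis` (3 x r), `density` (r x n), `objective`,
#'   `objective_trace`, `iterations`, `converged`.
#' @export
nmf_factorize <- function(od, r = 2, params = snmf_params()) {
  snmf_engine(od, r, 0, params)
}

#' Sparse non-negative matrix factorization of an OD image
#'
#' As [nmf_factorize()] but the density subproblem carries an l1 penalty
#' `lambda * sum_j ||S(j,:)||_1`, encouraging each pixel to use few stains.
#' Setting `lambda_sparsity = 0` reduces exactly to plain NMF.
#'
#' @inheritParams nmf_factorize
#' @param params an [snmf_params()] object supplying `lambda_sparsity`.
#' @return As [nmf_factorize()], plus `lambda`.
#' @export
snmf_factorize <- function(od, r = 2, params = snmf_params()) {
  snmf_engine(od, r, params$lambda_sparsity, params)
}

#' Grid search for the SNMF sparsity weight
#'
#' Runs [snmf_factorize()] at each candidate `lambda` and returns the value
#' minimizing the unpenalized reconstruction error.
#'
#' @inheritParams snmf_factorize
#' @param lambda_grid numeric vector of candidate penalties.
#' @return List with `lambda` (the selected value), `errors`, and `fit` (the
#'   winning factorization).
#' @export
snmf_lambda_search <- function(od, r = 2, lambda_grid = c(0, 0.01, 0.1, 0.5),
                               params = snmf_params()) {
  fits <- lapply(lambda_grid, function(l) {
    p <- params; p$lambda_sparsity <- l
    snmf_factorize(od, r, p)
  })
  errs <- vapply(fits, function(f) sqrt(sum((od - f$basis %*% f$density)^2)),
                 numeric(1))
  best <- which.min(errs)
  list(lambda = lambda_grid[best], errors = errs, fit = fits[[best]])
}
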