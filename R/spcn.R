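#' Pseudo-maximum of each stain-density row
#'
#' The pseudo-maximum RM(S) is the per-row empirical quantile of the density
#' map at a high level (default 99%), a robust stand-in for the row maximum.
#' Quantiles use linear interpolation between order statistics (R type 7),
#' since quantile dialects differ across ecosystems.
#'
#' @param S r x n non-negative density matrix.
#' @param quantile level in (0, 1\]; default 0.99.
#' @return Numeric vector of length r with attribute `quantile`.
#' @export
row_pseudo_max <- function(S, quantile = 0.99) {
  if (!is.matrix(S) || ncol(S) < 1L) stop("`S` must be a matrix with n >= 1")
  if (quantile <= 0 || quantile > 1) stop("`quantile` must be in (0, 1]")
  rm_ <- apply(S, 1, stats::quantile, probs = quantile, names = FALSE, type = 7)
  attr(rm_, "quantile") <- quantile
  rm_
}

#' Rescale source stain densities to target pseudo-maxima
#'
#' Row j of the source density map is multiplied by
#' `rm_target[j] / rm_source[j]`, so after rescaling the source's pseudo-
#' maximum matches the target's, stain by stain. A pure row scaling never
#' changes the support or the spatial pattern of any stain, which is what
#' makes the normalization structure-preserving.
#'
#' @param Ss r x n source density matrix.
#' @param rm_source,rm_target pseudo-maxima from [row_pseudo_max()] (length
#'   r).
#' @return Rescaled r x n density matrix.
#' @export
normalize_density <- function(Ss, rm_source, rm_target) {
  if (length(rm_source) != nrow(Ss) || length(rm_target) != nrow(Ss))
    stop("pseudo-maxima must have one entry per stain row")
  scale <- rep(1, nrow(Ss))
  for (j in seq_len(nrow(Ss))) {
    if (rm_source[j] <= 0) {
      if (any(Ss[j, ] > 0))
        stop(sprintf("degenerate stain %d: zero pseudo-maximum with non-zero density", j))
      warning(sprintf("stain %d has an all-zero density row; left unscaled", j))
    } else {
      scale[j] <- rm_target[j] / rm_source[j]
    }
  }
  Ss * scale
}

#' Structure-preserving color normalization of one image to a target
#'
#' Both images are factorized into stain basis x density ([snmf_factorize()]
#' with columns ordered by [order_stains()]); the source densities are
#' rescaled to the target's per-stain pseudo-maxima with
#' [normalize_density()]; and the normalized OD image is rebuilt from the
#' target basis, `OD_norm = V_target %*% S_source_norm`, then mapped back to
#' RGB. The source keeps its own spatial stain pattern (structure) but takes
#' on the target's stain colors and intensity scale.
#'
#' @param source,target H x W x 3 RGB arrays in \[0, 255\].
#' @param params an [snmf_params()] object used for both factorizations.
#' @param quantile pseudo-maximum level (default 0.99).
#' @param blank illuminant intensity for the Beer-Lambert transforms.
#' @param return_details if `TRUE`, also return the two factorizations and
#'   the normalized density map.
#' @return The normalized H x W x 3 image, or (with details) a list
#'   `image`, `source_fit`, `target_fit`, `density_norm`.
#' @export
spcn_normalize <- function(source, target, params = snmf_params(),
                           quantile = 0.99, blank = 255,
                           return_details = FALSE) {
  stopifnot_image(source, "source"); stopifnot_image(target, "target")
  od_s <- od_flatten(rgb_to_od(source, blank))
  od_t <- od_flatten(rgb_to_od(target, blank))
  fit_s <- snmf_factorize(od_s, 2, params)
  fit_t <- snmf_factorize(od_t, 2, params)
  # align stain correspondence via the canonical ordering
  Vs <- order_stains(fit_s$basis)
  Vt <- order_stains(fit_t$basis)
  # The l1 penalty serves basis identification; reconstructing from penalized
  # densities would bias every stained pixel brighter by the shrinkage. The
  # density maps used for normalization are therefore the unpenalized
  # non-negative projections onto the learned bases.
  Ss <- sparse_code(od_s, Vs, 0)
  St <- sparse_code(od_t, Vt, 0)
  Ss_norm <- normalize_density(Ss, row_pseudo_max(Ss, quantile),
                               row_pseudo_max(St, quantile))
  od_norm <- Vt %*% Ss_norm
  attr(od_norm, "dim_hw") <- dim(source)[1:2]
  img <- od_to_rgb(od_unflatten(od_norm), blank)
  if (!return_details) return(img)
  list(image = img, source_fit = list(basis = Vs, density = Ss, fit = fit_s),
       target_fit = list(basis = Vt, density = St, fit = fit_t),
       density_norm = Ss_norm)
}
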