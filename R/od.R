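#' Beer-Lambert transform: RGB intensities to optical density
#'
#' Converts 8-bit-scale RGB intensities to optical densities via the
#' Beer-Lambert law, `OD = -log(I / I_blank)`, channelwise. Optical density is
#' linear in stain concentration, unlike raw RGB, and is the working space for
#' stain separation. Intensities are clamped below at 1 before the log so that
#' black pixels map to the finite ceiling `log(blank)` (about 5.54 for 8-bit
#' images) rather than infinity.
#'
#' @param image numeric H x W x 3 array of intensities in \[0, 255\].
#' @param blank illuminant (blank-field) intensity per channel; scalar or
#'   length-3, strictly positive. Default 255, the usual value for 8-bit
#'   images.
#' @return H x W x 3 array of non-negative optical densities with attribute
#'   `blank`.
#' @seealso [od_to_rgb()] for the inverse transform.
#' @examples
#' od <- rgb_to_od(array(128, dim = c(4, 4, 3)))
#' range(od)
#' @export
rgb_to_od <- function(image, blank = 255) {
  stopifnot_image(image)
  blank <- check_blank(blank)
  bl <- rep(blank, length.out = 3L)
  od <- image
  for (k in 1:3) {
    i <- pmin(pmax(image[, , k], 1), bl[k])
    od[, , k] <- -log(i / bl[k])
  }
  attr(od, "blank") <- bl
  od
}

#' Inverted Beer-Lambert transform: optical density to RGB
#'
#' Maps optical densities back to 8-bit-scale intensities,
#' `I = blank * exp(-OD)`, clipped to \[0, 255\]. Monotonically decreasing in
#' OD; composing with [rgb_to_od()] is the identity on intensities in
#' \[1, 255\] up to floating-point rounding.
#'
#' @param od numeric H x W x 3 array of non-negative optical densities.
#' @param blank illuminant intensity per channel (scalar or length 3, > 0).
#' @return H x W x 3 array of intensities in \[0, 255\].
#' @export
od_to_rgb <- function(od, blank = 255) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("`od` must be an H x W x 3 array", call. = FALSE)
  if (!all(is.finite(od))) stop("`od` contains non-finite values", call. = FALSE)
  if (min(od) < -1e-9) stop("`od` must be non-negative", call. = FALSE)
  blank <- check_blank(blank)
  bl <- rep(blank, length.out = 3L)
  img <- od
  for (k in 1:3) img[, , k] <- pmin(pmax(bl[k] * exp(-pmax(od[, , k], 0)), 0), 255)
  img
}

check_blank <- function(blank) {
  if (!is.numeric(blank) || !length(blank) %in% c(1L, 3L) ||
      any(!is.finite(blank)) || any(blank <= 0))
    stop("`blank` must be a positive scalar or length-3 vector", call. = FALSE)
  blank
}

#' Flatten an OD image to a 3 x n pixel matrix
#'
#' Stain separation works on a 3 x n matrix whose columns are per-pixel OD
#' triples. Pixels are taken in R's column-major order; [od_unflatten()]
#' restores the image layout.
#'
#' @param od H x W x 3 OD array.
#' @return 3 x (H*W) matrix with attribute `dim_hw = c(H, W)`.
#' @export
od_flatten <- function(od) {
  d <- dim(od)
  m <- t(matrix(od, ncol = 3L))
  attr(m, "dim_hw") <- d[1:2]
  m
}

#' @rdname od_flatten
#' @param m 3 x n OD matrix.
#' @param dim_hw integer c(H, W); defaults to the attribute left by
#'   [od_flatten()].
#' @export
od_unflatten <- function(m, dim_hw = attr(m, "dim_hw")) {
  if (is.null(dim_hw)) stop("image dimensions unknown; pass `dim_hw`")
  array(t(m), dim = c(dim_hw[1], dim_hw[2], 3L))
}
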