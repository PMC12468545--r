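#' Parameters for STRESS contrast stretching
#'
#' STRESS (Spatio-Temporal Retinex-like Envelope with Stochastic Sampling)
#' estimates, for every pixel, local black and white envelope points from
#' random "sprays" of samples and stretches the pixel between them.
#'
#' @param radius sampling-disk radius R in pixels (>= 1). `NULL` (default)
#'   means "use max(H, W) of the image", which reads the whole image as one
#'   illumination context and behaves like a randomized global stretch.
#' @param samples number of spray samples M per iteration (>= 1).
#' @param iterations number of sprays N averaged per pixel (>= 1). Larger M, N
#'   average out sampling noise at linear cost.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list of class `stress_params`.
#' @export
stress_params <- function(radius = NULL, samples = 30, iterations = 100,
                          seed = NULL) {
  if (!is.null(radius) && (!is.numeric(radius) || radius < 1))
    stop("`radius` must be >= 1")
  if (samples < 1 || iterations < 1)
    stop("`samples` and `iterations` must be >= 1")
  structure(list(radius = radius, samples = as.integer(samples),
                 iterations = as.integer(iterations), seed = seed),
            class = "stress_params")
}

#' Draw one random spray of sample coordinates
#'
#' Samples `params$samples` pixel coordinates uniformly over the disk of
#' radius R around `center` (radius drawn as `R * sqrt(u)` so density is
#' uniform over the disk area). Draws falling outside the image, or hitting
#' the center itself, are redrawn up to a bounded retry count and then clamped
#' to the border; a clamped draw that still coincides with the center is
#' dropped (so a 1 x 1 image yields an empty spray).
#'
#' @param center numeric c(x, y), 0-based pixel coordinate (column, row).
#' @param params a [stress_params()] object (its `radius` must be set).
#' @param extent numeric c(width, height) of the image.
#' @return Integer matrix with columns `x`, `y` (0-based), one row per sample.
#' @export
sample_spray <- function(center, params, extent) {
  R <- params$radius
  if (is.null(R)) stop("`params$radius` must be set for sample_spray")
  w <- extent[1]; h <- extent[2]
  if (center[1] < 0 || center[1] >= w || center[2] < 0 || center[2] >= h)
    stop("`center` must lie inside the image")
  out <- matrix(NA_integer_, nrow = 0, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  for (s in seq_len(params$samples)) {
    x <- y <- -1L; ok <- FALSE
    for (t in 1:20) {
      theta <- 2 * pi * runif(1)
      rad <- R * sqrt(runif(1))
      x <- as.integer(round(center[1] + rad * cos(theta)))
      y <- as.integer(round(center[2] + rad * sin(theta)))
      if (x >= 0 && x < w && y >= 0 && y < h &&
          !(x == center[1] && y == center[2])) { ok <- TRUE; break }
    }
    if (!ok) {
      x <- min(max(x, 0L), as.integer(w) - 1L)
      y <- min(max(y, 0L), as.integer(h) - 1L)
      if (x == center[1] && y == center[2]) next
    }
    out <- rbind(out, c(x, y))
  }
  out
}

#' STRESS-stretch a single scalar channel
#'
#' Applies the STRESS update to every pixel of one channel: per iteration a
#' spray is drawn, the sample range r_i and the relative position v_i of the
#' pixel inside that range are computed (v_i = 1/2 for a zero range), the N
#' iterations are averaged into envelopes Emin = p0 - v.bar * r.bar and
#' Emax = Emin + r.bar, and the output is (p0 - Emin) / (Emax - Emin), clipped
#' to \[0, 1\]. A constant channel maps to 0.5 everywhere (the zero-range
#' limit).
#'
#' @param channel numeric H x W matrix with finite values.
#' @param params a [stress_params()] object.
#' @return H x W matrix with values in \[0, 1\].
#' @export
stress_channel <- function(channel, params = stress_params()) {
  if (!is.matrix(channel) || !all(is.finite(channel)))
    stop("`channel` must be a finite numeric matrix")
  R <- if (is.null(params$radius)) max(dim(channel)) else params$radius
  # the compiled kernel uses its own RNG stream; seeding that stream from R's
  # RNG keeps the (input, params, seed) -> output contract
  stream_seed <- with_seed(params$seed, floor(runif(1) * 2^53))
  .stress_channel_cpp(channel, R, params$samples, params$iterations,
                      stream_seed)
}

#' STRESS-stretch an RGB image
#'
#' Scales the image to \[0, 1\], applies [stress_channel()] independently to
#' each channel, and rescales to \[0, 255\]. By default each channel gets its
#' own RNG stream derived from `params$seed` (seed, seed + 1, seed + 2);
#' `share_channel_seed = TRUE` reuses the same stream for all three channels,
#' so a gray image stays gray.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param params a [stress_params()] object.
#' @param share_channel_seed logical; see Details.
#' @return H x W x 3 array in \[0, 255\].
#' @export
stress_image <- function(image, params = stress_params(),
                         share_channel_seed = FALSE) {
  stopifnot_image(image)
  out <- image
  for (k in 1:3) {
    p <- params
    if (!is.null(params$seed) && !share_channel_seed)
      p$seed <- params$seed + (k - 1L)
    out[, , k] <- 255 * stress_channel(image[, , k] / 255, p)
  }
  out
}
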