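#' Configuration for synthetic IHC scene generation
#'
#' The generator emulates the structure the real study images share: a
#' near-white background, disk-like nuclei, and two stains — hematoxylin
#' (blue, immunonegative nuclei) and DAB (brown, immunopositive nuclei) —
#' mixed linearly in optical-density space with a known basis, plus additive
#' Gaussian OD noise. Every scene carries its full ground truth (mask,
#' per-nucleus labels, true basis and density maps), so the estimators in
#' this package can be tested against the generating model.
#'
#' @param height,width image size in pixels (default 256 x 256).
#' @param n_nuclei number of non-overlapping disk nuclei (default 25).
#' @param radius_range nucleus radius range in pixels (default 8-16).
#' @param fraction_positive fraction of nuclei labeled immunopositive
#'   (default 0.5).
#' @param main_density_range peak OD density range of a nucleus's own stain
#'   (default 0.8-1.2).
#' @param cross_density_range peak density of the opposite stain inside a
#'   nucleus (default 0, i.e. each nucleus class carries only its own stain;
#'   set e.g. c(0.05, 0.25) to emulate counterstain bleed-through).
#' @param background_density flat density of both stains outside nuclei
#'   (default 0.01; 0 gives a pure-white background).
#' @param noise_sigma standard deviation of additive Gaussian OD noise
#'   (default 0.01).
#' @param basis 3 x 2 stain basis; defaults to the canonical
#'   hematoxylin/DAB unit vectors.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(height = 256, width = 256, n_nuclei = 25,
                         radius_range = c(8, 16), fraction_positive = 0.5,
                         main_density_range = c(0.8, 1.2),
                         cross_density_range = c(0, 0),
                         background_density = 0.01, noise_sigma = 0.01,
                         basis = cbind(CANONICAL_HEMATOXYLIN, CANONICAL_DAB),
                         seed = 1) {
  if (any(radius_range < 1) || radius_range[1] > radius_range[2])
    stop("invalid `radius_range`")
  if (any(main_density_range < 0) || any(cross_density_range < 0) ||
      background_density < 0 || noise_sigma < 0)
    stop("densities and noise must be >= 0")
  if (fraction_positive < 0 || fraction_positive > 1)
    stop("`fraction_positive` must be in [0, 1]")
  colnames(basis) <- c("hematoxylin", "dab")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei), radius_range = radius_range,
                 fraction_positive = fraction_positive,
                 main_density_range = main_density_range,
                 cross_density_range = cross_density_range,
                 background_density = background_density,
                 noise_sigma = noise_sigma, basis = basis, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic two-stain IHC scene with ground truth
#'
#' Places non-overlapping disk nuclei by rejection sampling (bounded
#' retries), gives immunonegative nuclei a high hematoxylin density and
#' immunopositive nuclei a high DAB density with a cosine radial falloff
#' (peak at the center, zero at the rim), adds a flat background density and
#' Gaussian OD noise (clamped at zero), and renders the image through the
#' inverted Beer-Lambert transform, rounded to 8-bit levels.
#'
#' @param config a [synth_config()] object.
#' @return Object of class `ihc_scene`: `image` (H x W x 3, integers in
#'   0-255), `od` (the rendered 3 x n OD matrix including noise),
#'   `nuclei_mask` (H x W, 0/1), `nuclei` (data frame: 0-based `x`, `y`,
#'   `radius`, `label`), `true_basis` (3 x 2, hematoxylin first),
#'   `true_density` (2 x n, noiseless), `noise_sigma`, `seed`, `config`.
#' @export
make_scene <- function(config = synth_config()) {
  h <- config$height; w <- config$width
  with_seed(config$seed, {
    rr <- config$radius_range
    nuclei <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
    tries <- 0L
    max_tries <- 400L * max(config$n_nuclei, 1L)
    while (nrow(nuclei) < config$n_nuclei) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("packing failure: could not place the requested nuclei; ",
             "reduce n_nuclei or radius_range")
      r <- runif(1, rr[1], rr[2])
      x <- runif(1, r, w - 1 - r)
      y <- runif(1, r, h - 1 - r)
      if (nrow(nuclei) == 0 ||
          all((nuclei$x - x)^2 + (nuclei$y - y)^2 > (nuclei$radius + r + 1)^2))
        nuclei <- rbind(nuclei, data.frame(x = x, y = y, radius = r))
    }
    n_pos <- round(config$n_nuclei * config$fraction_positive)
    labels <- c(rep("+", n_pos), rep("-", config$n_nuclei - n_pos))
    nuclei$label <- if (config$n_nuclei > 0) sample(labels) else character(0)

    # pixel grids (0-based coordinates, column-major pixel order)
    ys <- matrix(0:(h - 1), h, w)
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
    S <- matrix(config$background_density, 2, h * w,
                dimnames = list(c("hematoxylin", "dab"), NULL))
    mask <- matrix(0L, h, w)
    for (i in seq_len(nrow(nuclei))) {
      d <- sqrt((xs - nuclei$x[i])^2 + (ys - nuclei$y[i])^2)
      inside <- d <= nuclei$radius[i]
      mask[inside] <- 1L
      falloff <- cos(pi / 2 * d[inside] / nuclei$radius[i])
      main <- runif(1, config$main_density_range[1], config$main_density_range[2])
      cross <- runif(1, config$cross_density_range[1], config$cross_density_range[2])
      rows <- if (nuclei$label[i] == "+") c(main = 2L, cross = 1L)
              else c(main = 1L, cross = 2L)
      idx <- which(inside)
      S[rows["main"], idx] <- S[rows["main"], idx] + main * falloff
      S[rows["cross"], idx] <- S[rows["cross"], idx] + cross * falloff
    }
    od <- config$basis %*% S
    if (config$noise_sigma > 0)
      od <- od + rnorm(length(od), sd = config$noise_sigma)
    od <- pmax(od, 0)
    attr(od, "dim_hw") <- c(h, w)
    image <- round(od_to_rgb(od_unflatten(od)))
    structure(list(image = image, od = od, nuclei_mask = mask,
                   nuclei = nuclei, true_basis = config$basis,
                   true_density = S, noise_sigma = config$noise_sigma,
                   seed = config$seed, config = config),
              class = "ihc_scene")
  })
}

#' @export
print.ihc_scene <- function(x, ...) {
  cat(sprintf("Synthetic IHC scene: %d x %d, %d nuclei (%d +, %d -), noise sigma %.3g\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$nuclei),
              sum(x$nuclei$label == "+"), sum(x$nuclei$label == "-"),
              x$noise_sigma))
  invisible(x)
}

#' @export
plot.ihc_scene <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(x$image)[1] / dim(x$image)[2])
  graphics::rasterImage(x$image / 255, 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

#' Extract center-point annotations from a synthetic scene
#'
#' One annotation per nucleus, at its (rounded) center, with the generating
#' immunopositive/immunonegative label — the format pathologist point
#' annotations use.
#'
#' @param scene an `ihc_scene` from [make_scene()].
#' @return Data frame with 0-based integer columns `x`, `y` and `label`.
#' @export
scene_to_annotations <- function(scene) {
  if (nrow(scene$nuclei) < 1L) stop("scene has no nuclei to annotate")
  data.frame(x = as.integer(round(scene$nuclei$x)),
             y = as.integer(round(scene$nuclei$y)),
             label = scene$nuclei$label, stringsAsFactors = FALSE)
}
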