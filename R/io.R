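#' Read an RGB image
#'
#' Reads PNG, JPEG or TIFF into the package's working representation: a
#' numeric H x W x 3 array on the \[0, 255\] scale. Grayscale inputs are
#' promoted to three identical channels; an alpha channel is dropped with a
#' warning; 16-bit PNG/TIFF inputs are rescaled to the 8-bit range with a
#' warning.
#'
#' @param path image file (.png, .jpg/.jpeg, .tif/.tiff).
#' @return H x W x 3 numeric array in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      warning(sprintf("'%s' is %d-bit; rescaled to 8-bit", path, info$bit.depth))
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample")
    if (!is.null(bits) && bits > 8)
      warning(sprintf("'%s' is %d-bit; rescaled to 8-bit", path, bits))
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores (x, y[, c]); convert to (row, col[, c])
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] == 2L) {  # gray + alpha
    warning(sprintf("dropping alpha channel of '%s'", path))
    a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3L))
  }
  if (dim(a)[3] == 4L) {
    warning(sprintf("dropping alpha channel of '%s'", path))
    a <- a[, , 1:3, drop = FALSE]
  }
  attributes(a) <- list(dim = dim(a))   # drop reader metadata
  a * 255
}

#' Write an RGB image
#'
#' Writes the H x W x 3 \[0, 255\] array to PNG (lossless, the canonical
#' intermediate format), TIFF, or JPEG, chosen by file extension. Values are
#' rounded to 8-bit levels on write.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot_image(image)
  a <- round(image) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else if (ext %in% c("jpg", "jpeg")) {
    EBImage::writeImage(EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color"),
                        path, quality = 95)
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
  invisible(path)
}

# Recursively overlay user-supplied config values on defaults, rejecting
# unknown keys and re-validating through the parameter constructors.
apply_config_section <- function(defaults, values, section, constructor) {
  if (is.null(values)) return(defaults)
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s' in section '%s'",
                 unknown[1], section))
  do.call(constructor, utils::modifyList(unclass(defaults)[
    setdiff(names(defaults), character(0))], values))
}

#' Load a pipeline configuration from YAML
#'
#' The file mirrors [pipeline_config()]: top-level keys `quantile`,
#' `min_area_fraction`, `seed` and sections `stress`, `snmf`, `rssfca` whose
#' keys match the corresponding parameter constructors. Missing keys take
#' the package defaults; unknown keys are rejected by name; every value is
#' re-validated through its constructor. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("stress", "snmf", "rssfca", "quantile", "min_area_fraction", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s'", unknown[1]))
  stress <- apply_config_section(stress_params(), y$stress, "stress", stress_params)
  snmf <- apply_config_section(snmf_params(), y$snmf, "snmf", snmf_params)
  rssfca <- apply_config_section(rssfca_params(), y$rssfca, "rssfca", rssfca_params)
  pipeline_config(stress = stress, snmf = snmf, rssfca = rssfca,
                  quantile = y$quantile %||% 0.99,
                  min_area_fraction = y$min_area_fraction %||% 1e-4,
                  seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config a [pipeline_config()] object.
#' @export
save_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(list(stress = strip(config$stress),
                        snmf = strip(config$snmf),
                        rssfca = strip(config$rssfca),
                        quantile = config$quantile,
                        min_area_fraction = config$min_area_fraction,
                        seed = config$seed), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to re-run a pipeline invocation bit-identically:
#' the full configuration snapshot (including the master seed), stage
#' convergence flags and timings, input/output paths, and an MD5 content
#' hash of each input file.
#'
#' @param path destination JSON path.
#' @param config a [pipeline_config()] object.
#' @param inputs named character vector of input file paths.
#' @param outputs named character vector of output file paths.
#' @param info optional per-stage info list (from [normalize_ihc()]).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           outputs = character(0), info = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "ihcnorm",
    version = as.character(utils::packageVersion("ihcnorm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = jsonlite::fromJSON(jsonlite::toJSON(
      list(stress = unclass(config$stress), snmf = unclass(config$snmf),
           rssfca = unclass(config$rssfca), quantile = config$quantile,
           min_area_fraction = config$min_area_fraction, seed = config$seed),
      auto_unbox = TRUE, null = "null")),
    inputs = as.list(inputs), input_md5 = hashes,
    outputs = as.list(outputs), stages = info)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
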