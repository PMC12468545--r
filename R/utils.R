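#' @useDynLib ihcnorm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd cor
#' @importFrom utils read.csv write.csv modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  invisible(image)
}

# Angle (degrees) between two vectors; recovery-error currency for stain bases.

#' Angle between two stain vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return Angle in degrees, in \[0, 180\].
#' @export
stain_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length vector has no direction")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

# Luma weights shared by grayscale conversion and background identification.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)
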