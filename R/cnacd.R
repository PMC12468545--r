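#' Unsupervised immunopositive/immunonegative pixel classification
#'
#' Classifies annotated nucleus pixels by automatic color deconvolution: the
#' stain basis is estimated from the whole image with
#' [macenko_stain_vectors()], per-pixel densities are
#' sparse-coded against it, each stain's rank-1 OD contribution is rebuilt
#' as an RGB image via the inverted Beer-Lambert transform, converted to
#' grayscale (luma weights 0.299/0.587/0.114), and the annotated pixel is
#' called immunonegative ("-") when the positive-stain (DAB) grayscale is
#' strictly lighter than the negative-stain grayscale, else immunopositive
#' ("+") — lighter grayscale means less stain, and ties go to "+".
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param annotations data frame with 0-based pixel columns `x` (column) and
#'   `y` (row); see [read_annotations()].
#' @param lambda1 sparse-coding penalty (default 0.1).
#' @param beta OD threshold for the stain-vector estimation (default 0.15).
#'   Pixels below it — the near-white background — are excluded from the
#'   basis estimate; without this exclusion the angle-percentile extremes are
#'   dominated by the arbitrary directions of noise-level background OD
#'   vectors and the estimate collapses. `NA` disables the filtering.
#' @param blank illuminant intensity.
#' @return Character vector of "+" / "-" labels, one per annotation.
#' @export
classify_pixels <- function(image, annotations, lambda1 = 0.1, beta = 0.15,
                            blank = 255) {
  stopifnot_image(image)
  if (nrow(annotations) < 1L) stop("need at least one annotation")
  d <- dim(image)
  if (any(annotations$x < 0 | annotations$x >= d[2] |
          annotations$y < 0 | annotations$y >= d[1]))
    stop("annotation coordinates fall outside the image")
  od <- od_flatten(rgb_to_od(image, blank))
  V <- macenko_stain_vectors(od, beta = beta)
  S <- sparse_code(od, V, lambda1)
  gray_of_stain <- function(j) {
    od_j <- V[, j, drop = FALSE] %*% S[j, , drop = FALSE]   # rank-1 OD
    attr(od_j, "dim_hw") <- d[1:2]
    img_j <- od_to_rgb(od_unflatten(od_j), blank)
    img_j[, , 1] * LUMA_WEIGHTS[1] + img_j[, , 2] * LUMA_WEIGHTS[2] +
      img_j[, , 3] * LUMA_WEIGHTS[3]
  }
  gray_neg <- gray_of_stain(which(colnames(V) == "hematoxylin"))
  gray_pos <- gray_of_stain(which(colnames(V) == "dab"))
  idx <- cbind(annotations$y + 1L, annotations$x + 1L)
  ifelse(gray_pos[idx] > gray_neg[idx], "-", "+")
}

#' Classification accuracy with confusion counts
#'
#' `AC = (TP + TN) / (TP + FN + TN + FP)`, treating "+" (immunopositive) as
#' the positive class.
#'
#' @param pred,truth equal-length character vectors of "+" / "-" labels.
#' @return List with `accuracy` and integer counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L)
    stop("`pred` and `truth` must be equal-length and non-empty")
  tp <- sum(pred == "+" & truth == "+")
  tn <- sum(pred == "-" & truth == "-")
  fp <- sum(pred == "+" & truth == "-")
  fn <- sum(pred == "-" & truth == "+")
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Read and write point annotations
#'
#' Annotations are CSV files with header `x,y,label`: 0-based pixel
#' coordinates (x = column, y = row, top-left origin) and optional "+"/"-"
#' labels.
#'
#' @param path file path.
#' @return `read_annotations`: data frame with columns `x`, `y` and, if
#'   present, `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop(sprintf("annotation file '%s' must have columns x,y", path))
  df
}

#' @rdname read_annotations
#' @param annotations data frame with columns `x`, `y` and optionally
#'   `label`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
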