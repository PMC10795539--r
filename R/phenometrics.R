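# Silhouette-based shape descriptors: fruit shape index (FSI), shoulder
# ratio (SR), and the five-class shape categorisation.

SHAPE_CATEGORIES <- c("flat", "flat-globose", "globose", "oval", "oblong")
DEFAULT_FSI_THRESHOLDS <- c(0.85, 0.95, 1.05, 1.20)

#' Extract the fruit silhouette from an image
#'
#' Converts to luminance, applies a global threshold (Otsu's method by
#' default), keeps the largest connected foreground component and fills its
#' holes.
#'
#' @param image an H x W x 3 array in [0, 1] (or an H x W grayscale matrix).
#' @param thresholdPolicy `"otsu"` for an automatic global threshold, or
#'   `"fixed"` for `fixedThreshold` (useful for decoded images with soft
#'   edges).
#' @param fixedThreshold threshold used when `thresholdPolicy = "fixed"`.
#' @param provenance label stored on the mask: `"original"`,
#'   `"decoded_mean"` or `"predicted"`.
#' @return a logical H x W matrix with attribute `provenance`.
#' @examples
#' m <- extractSilhouette(renderFruit(shapeParams(), imageSize = 128))
#' @export
extractSilhouette <- function(image, thresholdPolicy = c("otsu", "fixed"),
                              fixedThreshold = 0.5,
                              provenance = c("original", "decoded_mean",
                                             "predicted")) {
  thresholdPolicy <- match.arg(thresholdPolicy)
  provenance <- match.arg(provenance)
  gray <- if (length(dim(image)) == 3L) {
    0.2126 * image[, , 1L] + 0.7152 * image[, , 2L] + 0.0722 * image[, , 3L]
  } else image
  thr <- if (thresholdPolicy == "otsu") {
    EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  } else fixedThreshold
  mask <- gray > thr
  if (!any(mask)) stop("empty foreground after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  lab <- EBImage::imageData(lab) == keep
  filled <- EBImage::fillHull(EBImage::Image(lab))
  out <- t(EBImage::imageData(filled)) > 0
  structure(out, provenance = provenance)
}

mask_row_range <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) stop("empty silhouette mask", call. = FALSE)
  list(rows = range(rows), cols = range(cols))
}

#' Fruit shape index of a silhouette
#'
#' FSI is the silhouette height over its width: (bottom-most row - top-most
#' row + 1) / (right-most column - left-most column + 1).
#'
#' @param mask a logical H x W silhouette mask (see [extractSilhouette()]).
#' @return the FSI, a positive real.
#' @examples
#' fruitShapeIndex(matrix(TRUE, 120, 100))  # 1.2
#' @export
fruitShapeIndex <- function(mask) {
  r <- mask_row_range(mask)
  (r$rows[2L] - r$rows[1L] + 1) / (r$cols[2L] - r$cols[1L] + 1)
}

#' Shoulder ratio of a silhouette
#'
#' The ratio of the silhouette width near the top to its width near the
#' bottom. The extreme rows of a convex silhouette have near-zero width, so
#' the measurement rows are inset by `offsetFraction` of the height:
#' width at row `top + round(offsetFraction * height)` over width at row
#' `bottom - round(offsetFraction * height)`. Width is the horizontal extent
#' of the mask on the measurement row.
#'
#' @param mask a logical H x W silhouette mask.
#' @param offsetFraction measurement-row inset as a fraction of the height,
#'   in (0, 0.5).
#' @return the shoulder ratio, a positive real.
#' @export
shoulderRatio <- function(mask, offsetFraction = 0.10) {
  if (offsetFraction <= 0 || offsetFraction >= 0.5)
    stop("offsetFraction must lie in (0, 0.5)", call. = FALSE)
  r <- mask_row_range(mask)
  h <- r$rows[2L] - r$rows[1L] + 1
  inset <- round(offsetFraction * h)
  row_width <- function(row) {
    cols <- which(mask[row, ])
    if (!length(cols)) stop(sprintf("zero width at measurement row %d", row),
                            call. = FALSE)
    cols[length(cols)] - cols[1L] + 1
  }
  row_width(r$rows[1L] + inset) / row_width(r$rows[2L] - inset)
}

#' Classify an FSI value into one of five shape categories
#'
#' Interval lookup against four strictly increasing cut points `t1 < t2 < t3
#' < t4`: `fsi < t1` is flat, `[t1, t2)` flat-globose, `[t2, t3)` globose,
#' `[t3, t4)` oval, and `>= t4` oblong (left-closed intervals, so an FSI
#' exactly at a cut point falls in the upper class).
#'
#' @param fsi numeric vector of FSI values.
#' @param thresholds four strictly increasing cut points.
#' @return a factor with levels flat, flat-globose, globose, oval, oblong.
#' @examples
#' classifyShape(c(0.8, 0.9, 1.0, 1.1, 1.5))
#' @export
classifyShape <- function(fsi, thresholds = DEFAULT_FSI_THRESHOLDS) {
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be 4 strictly increasing cut points", call. = FALSE)
  idx <- findInterval(fsi, thresholds) + 1L
  factor(SHAPE_CATEGORIES[idx], levels = SHAPE_CATEGORIES)
}

#' Measure shape descriptors for every image in a set
#'
#' Batch driver: silhouette extraction, FSI, SR and category per image.
#'
#' @param x a [FruitImageSet-class], or a list of image arrays.
#' @param thresholds FSI category cut points (see [classifyShape()]).
#' @param thresholdPolicy,offsetFraction passed to [extractSilhouette()] and
#'   [shoulderRatio()].
#' @return a data.frame with columns imageId, genotypeId (NA for plain
#'   lists), fsi, sr, category.
#' @export
measureShapes <- function(x, thresholds = DEFAULT_FSI_THRESHOLDS,
                          thresholdPolicy = "otsu", offsetFraction = 0.10) {
  if (is(x, "FruitImageSet")) {
    imgs <- x@images; gids <- x@genotypeId; iids <- x@imageId
  } else {
    imgs <- x; gids <- rep(NA_character_, length(x))
    iids <- as.character(seq_along(x))
  }
  fsi <- sr <- numeric(length(imgs))
  for (i in seq_along(imgs)) {
    m <- extractSilhouette(imgs[[i]], thresholdPolicy = thresholdPolicy)
    fsi[i] <- fruitShapeIndex(m)
    sr[i] <- shoulderRatio(m, offsetFraction)
  }
  data.frame(imageId = iids, genotypeId = gids, fsi = fsi, sr = sr,
             category = classifyShape(fsi, thresholds),
             stringsAsFactors = FALSE)
}
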