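# Image loading, preprocessing, and the genotype-level stratified split.

#' Construct a FruitImageSet
#'
#' @param images list of H x W x 3 arrays in [0, 1].
#' @param genotypeId,imageId character vectors, one entry per image.
#' @return a [FruitImageSet-class].
#' @export
fruitImageSet <- function(images, genotypeId, imageId = NULL) {
  if (is.null(imageId)) {
    imageId <- stats::ave(seq_along(genotypeId), genotypeId,
                          FUN = seq_along)
    imageId <- as.character(imageId)
  }
  new("FruitImageSet", images = images,
      genotypeId = as.character(genotypeId), imageId = as.character(imageId))
}

# pad to square with a constant value, keeping the content centred
pad_to_square <- function(img, value) {
  d <- dim(img)
  side <- max(d[1:2])
  if (d[1L] == d[2L]) return(img)
  out <- array(value, c(side, side, d[3L]))
  r0 <- (side - d[1L]) %/% 2
  c0 <- (side - d[2L]) %/% 2
  out[r0 + seq_len(d[1L]), c0 + seq_len(d[2L]), ] <- img
  out
}

# resize an [H, W, 3] array with bilinear filtering
resize_rgb <- function(img, target) {
  if (dim(img)[1L] == target && dim(img)[2L] == target) return(img)
  ebi <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(ebi, w = target, h = target)
  out <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Load a directory of single-fruit images
#'
#' Reads every PNG/JPEG in `path`, parsing genotype and image ids from
#' filenames of the form `<genotypeId>_<imageId>.<ext>` (the image id is the
#' part after the last underscore). Non-square inputs are padded to a square
#' with the background value (the median intensity of the image border)
#' before bilinear resizing, so the fruit aspect ratio -- and hence its shape
#' index -- is preserved.
#'
#' @param path directory of images.
#' @param targetSize output side in pixels (images are returned square).
#' @return a [FruitImageSet-class].
#' @export
loadImageDir <- function(path, targetSize = 300L) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  targetSize <- assert_count(targetSize, "targetSize", min = 16L)
  files <- list.files(path, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  if (!length(files)) stop("no PNG/JPEG images in ", path, call. = FALSE)
  m <- regmatches(files,
                  regexec("^(.+)_([^_]+)\\.(png|jpe?g)$", files,
                          ignore.case = TRUE))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("filename(s) not of the form <genotypeId>_<imageId>.<ext>: ",
         paste(files[bad], collapse = ", "), call. = FALSE)
  gids <- vapply(m, `[`, character(1), 2L)
  iids <- vapply(m, `[`, character(1), 3L)
  images <- vector("list", length(files))
  for (i in seq_along(files)) {
    raw <- EBImage::readImage(file.path(path, files[i]))
    arr <- EBImage::imageData(raw)
    if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
    if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3]   # drop alpha
    arr <- aperm(arr, c(2L, 1L, 3L))              # to [H, W, 3]
    border <- c(arr[1L, , ], arr[dim(arr)[1L], , ],
                arr[, 1L, ], arr[, dim(arr)[2L], ])
    arr <- pad_to_square(arr, stats::median(border))
    arr <- resize_rgb(arr, targetSize)
    images[[i]] <- arr
  }
  fruitImageSet(images, gids, iids)
}

#' Genotype-level stratified train/validation split
#'
#' Assigns whole genotypes (never single images) to train or validation so
#' that each shape stratum's genotype count is divided as close to
#' `trainFraction` as integer rounding allows, preserving the overall shape
#' distribution in both partitions. When `strata` is not supplied it is
#' computed from the images: the per-genotype mean FSI is classified with
#' [classifyShape()]. A stratum holding a single genotype goes entirely to
#' train, with a warning.
#'
#' @param images a [FruitImageSet-class].
#' @param trainFraction fraction of genotypes per stratum sent to train.
#' @param strata optional named character/factor: stratum label per genotype.
#' @param thresholds FSI category cut points used when computing strata.
#' @param seed integer seed; assignments are deterministic given it.
#' @return a [DatasetSplit-class].
#' @export
stratifiedSplit <- function(images, trainFraction = 0.9, strata = NULL,
                            thresholds = DEFAULT_FSI_THRESHOLDS, seed = 1L) {
  stopifnot(is(images, "FruitImageSet"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)", call. = FALSE)
  gids <- unique(images@genotypeId)
  if (is.null(strata)) {
    sh <- measureShapes(images, thresholds = thresholds)
    mu <- tapply(sh$fsi, sh$genotypeId, mean)
    strata <- as.character(classifyShape(as.numeric(mu), thresholds))
    names(strata) <- names(mu)
  }
  if (!all(gids %in% names(strata)))
    stop("strata must label every genotype", call. = FALSE)
  strata <- strata[gids]
  train <- character(0)
  val <- character(0)
  with_seed(seed, {
    for (s in unique(strata)) {
      members <- gids[strata == s]
      if (length(members) == 1L) {
        warning(sprintf(
          "stratum '%s' has a single genotype; assigned to train", s),
          call. = FALSE)
        train <- c(train, members)
        next
      }
      n_train <- round(trainFraction * length(members))
      n_train <- min(max(n_train, 0L), length(members))
      picked <- sample(members, n_train)
      train <- c(train, picked)
      val <- c(val, setdiff(members, picked))
    }
  })
  new("DatasetSplit", trainGenotypes = train, valGenotypes = val,
      trainFraction = trainFraction)
}

#' Write a split manifest as CSV
#'
#' @param split a [DatasetSplit-class].
#' @param path output path; columns genotypeId, partition.
#' @return invisibly, `path`.
#' @export
writeSplitManifest <- function(split, path) {
  stopifnot(is(split, "DatasetSplit"))
  df <- data.frame(
    genotypeId = c(split@trainGenotypes, split@valGenotypes),
    partition = rep(c("train", "validation"),
                    c(length(split@trainGenotypes),
                      length(split@valGenotypes))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# stack a FruitImageSet (or list of arrays) into an [H, W, 3, N] array
stack_images <- function(x) {
  imgs <- if (is(x, "FruitImageSet")) x@images else x
  d <- dim(imgs[[1L]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}
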