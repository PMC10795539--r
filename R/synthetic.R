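# Parametric fruit-silhouette renderer and population simulator.
#
# The silhouette family is a superellipse with a linear vertical taper and
# optional sinusoidal radial lobing. The taper coefficient is solved in
# closed form from the target shoulder ratio, and the horizontal scale from
# the target fruit shape index, so both descriptors are analytically
# controllable and render-then-measure round trips are exact up to pixel
# quantisation.

SUPERELLIPSE_N <- 2.5
SR_INSET <- 0.10       # must match the shoulderRatio() default offset
FRUIT_EXTENT <- 0.80   # max silhouette extent as a fraction of image size
FLESH_RGB <- c(0.92, 0.84, 0.55)
SKIN_RGB <- c(0.85, 0.45, 0.35)
BACKGROUND_GREY <- 0.05

#' Construct shape parameters for the synthetic fruit renderer
#'
#' @param fsi target fruit shape index (silhouette height / width), positive.
#' @param sr target shoulder ratio (width at the top measurement row / width
#'   at the bottom measurement row, rows inset 10\% of the height), positive.
#' @param lobing sinusoidal radial lobing amplitude, fraction of local width,
#'   in [0, 0.2].
#' @param rotation rotation jitter in degrees: the rendered fruit is rotated
#'   by an angle drawn uniformly from [-rotation, rotation].
#' @return a [ShapeParams-class] object.
#' @examples
#' shapeParams(fsi = 1.1, sr = 1.2)
#' @export
shapeParams <- function(fsi = 1, sr = 1, lobing = 0, rotation = 0) {
  new("ShapeParams",
      fsi = assert_scalar_number(fsi, "fsi"),
      sr = assert_scalar_number(sr, "sr"),
      lobing = assert_scalar_number(lobing, "lobing", 0, 0.2),
      rotation = assert_scalar_number(rotation, "rotation"))
}

# taper coefficient solving (1 + c*tm)/(1 - c*tm) = sr at the measurement
# inset tm (normalised height coordinate of the shoulder-ratio rows)
taper_coef <- function(sr, inset = SR_INSET) {
  tm <- 1 - 2 * inset
  (sr - 1) / (tm * (sr + 1))
}

# half-width profile at normalised height t in [-1, 1] (t = +1 is the top),
# relative to the equatorial half-width
profile_halfwidth <- function(t, cc, n = SUPERELLIPSE_N) {
  (pmax(0, 1 - abs(t)^n))^(1 / n) * (1 + cc * t)
}

#' Render a synthetic single-fruit image
#'
#' Draws one fruit (superellipse with linear vertical taper and optional
#' sinusoidal lobing) on a uniform dark background, with a flesh-coloured
#' fill and a thin skin rim so that simple global thresholding recovers the
#' silhouette. The fruit is scaled so its larger extent is 80\% of the image;
#' rendering then measuring a `lobing = 0` shape recovers the target FSI and
#' SR to pixel accuracy.
#'
#' @param params a [ShapeParams-class] object (see [shapeParams()]).
#' @param imageSize square image side in pixels, at least 64.
#' @param seed integer seed for the rotation jitter draw (unused when
#'   `rotation = 0`).
#' @return an `imageSize x imageSize x 3` array in [0, 1], with attributes
#'   `trueArea` (silhouette area in pixels, from fine quadrature of the shape
#'   function rather than from the rasterised mask), `extents` (realised
#'   height and width in pixels) and `angle` (the rotation actually applied).
#' @examples
#' img <- renderFruit(shapeParams(fsi = 0.9), imageSize = 128)
#' @export
renderFruit <- function(params, imageSize = 300L, seed = NULL) {
  stopifnot(is(params, "ShapeParams"))
  validObject(params)
  imageSize <- assert_count(imageSize, "imageSize", min = 64L)

  cc <- taper_coef(params@sr)
  if (abs(cc) >= 0.99)
    stop("sr target implies a degenerate taper", call. = FALSE)
  tg <- seq(-1, 1, length.out = 2001L)
  m_rel <- max(profile_halfwidth(tg, cc))   # max half-width / equatorial

  # scale so the larger extent is FRUIT_EXTENT * imageSize
  if (params@fsi >= 1) {
    b <- FRUIT_EXTENT * imageSize / 2
    a0 <- b / (params@fsi * m_rel)
  } else {
    a0 <- FRUIT_EXTENT * imageSize / (2 * m_rel)
    b <- params@fsi * a0 * m_rel
  }
  height <- 2 * b
  width <- 2 * a0 * m_rel
  if (min(height, width) < 0.45 * imageSize)
    stop(sprintf(
      "degenerate shape: fsi %.3g puts the minor extent at %.0f px (< 45%% of a %d px canvas)",
      params@fsi, min(height, width), imageSize), call. = FALSE)

  angle <- 0
  if (params@rotation != 0) {
    angle <- with_seed(seed,
      stats::runif(1, -params@rotation, params@rotation)) * pi / 180
  }

  ctr <- (imageSize + 1) / 2
  px <- seq_len(imageSize)
  xg <- matrix(rep(px - ctr, each = imageSize), imageSize)   # column offset
  yg <- matrix(rep(ctr - px, times = imageSize), imageSize)  # row offset, up
  if (angle != 0) {
    xr <- cos(angle) * xg + sin(angle) * yg
    yr <- -sin(angle) * xg + cos(angle) * yg
  } else {
    xr <- xg; yr <- yg
  }

  inside_at <- function(shrink = 0) {
    t <- yr / b
    w <- a0 * profile_halfwidth(t, cc)
    if (params@lobing > 0) {
      theta <- atan2(xr, yr)
      w <- w * (1 + params@lobing * cos(5 * theta))
    }
    abs(t) <= 1 & abs(xr) <= pmax(0, w - shrink)
  }
  inside <- inside_at(0)
  core <- inside_at(2.5)   # everything not within ~2.5 px of the boundary

  img <- array(BACKGROUND_GREY, c(imageSize, imageSize, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- SKIN_RGB[ch]
    plane[core] <- FLESH_RGB[ch]
    img[, , ch] <- plane
  }

  true_area <- silhouette_area(a0, b, cc, params@lobing)
  structure(img, trueArea = true_area,
            extents = c(height = height, width = width), angle = angle)
}

# Silhouette area in squared pixels. Exact 1-D quadrature of the half-width
# profile for unlobed shapes; fine 2-D quadrature (independent of the image
# raster) otherwise.
silhouette_area <- function(a0, b, cc, lobing) {
  if (lobing == 0) {
    t <- seq(-1, 1, length.out = 20001L)
    w <- profile_halfwidth(t, cc)
    return(2 * a0 * b * mean(w) * 2)  # int_{-1}^{1} 2*a0*w dt * b
  }
  n <- 4L * 1024L
  xs <- seq(-a0 * (1 + lobing) * 1.05, a0 * (1 + lobing) * 1.05,
            length.out = 1025L)
  ts <- seq(-1, 1, length.out = n + 1L)
  w <- a0 * profile_halfwidth(ts, cc)
  acc <- 0
  dx <- diff(xs)[1L]
  for (i in seq_along(ts)) {
    theta <- atan2(xs, ts[i] * b)
    wl <- w[i] * (1 + lobing * cos(5 * theta))
    acc <- acc + sum(abs(xs) <= wl) * dx
  }
  acc * (2 * b / n)
}

#' Construct the additive genetic architecture of a simulated population
#'
#' @param nCausal number of causal SNPs (additive effects on the FSI).
#' @param nNeutral number of neutral SNPs.
#' @param effectSizes numeric of length `nCausal`: change in FSI per unit of
#'   dosage on the 0/0.5/1 scale.
#' @param baselineFsi FSI of the zero-dosage genotype.
#' @param envSd within-genotype (per image) FSI standard deviation.
#' @param alleleFreqs allele frequencies in (0, 1), recycled across SNPs.
#' @return a [GeneticArchitecture-class] object.
#' @examples
#' geneticArchitecture(10, 140, effectSizes = rep(0.03, 10))
#' @export
geneticArchitecture <- function(nCausal, nNeutral, effectSizes,
                                baselineFsi = 0.95, envSd = 0.03,
                                alleleFreqs = 0.5) {
  nCausal <- assert_count(nCausal, "nCausal")
  nNeutral <- assert_count(nNeutral, "nNeutral")
  new("GeneticArchitecture", nCausal = nCausal, nNeutral = nNeutral,
      effectSizes = as.numeric(effectSizes),
      baselineFsi = assert_scalar_number(baselineFsi, "baselineFsi"),
      envSd = assert_scalar_number(envSd, "envSd", lower = 0),
      alleleFreqs = rep_len(as.numeric(alleleFreqs), nCausal + nNeutral))
}

#' Simulate a genotyped fruit population with rendered images
#'
#' Draws genotypes under Hardy-Weinberg equilibrium from the architecture's
#' allele frequencies, maps them additively to a per-genotype FSI
#' (`baselineFsi + sum(effects * dosage)`), renders `imagesPerGenotype`
#' images per genotype with independent `N(0, envSd)` environmental noise on
#' the FSI, and returns the genotype matrix, the image set, and the true
#' per-genotype mean shape for parameter-recovery tests. Fully reproducible
#' from `seed`. Per-image FSI values are clamped to the renderer's valid
#' [0.6, 1.7] band; the shoulder ratio is held at 1 (environmental noise acts
#' on the FSI only).
#'
#' @param arch a [GeneticArchitecture-class] (see [geneticArchitecture()]).
#' @param nGenotypes number of genotypes (at least 2).
#' @param imagesPerGenotype images rendered per genotype (at least 1).
#' @param imageSize square image side in pixels.
#' @param seed integer seed driving genotype draws and environmental noise.
#' @return a list with elements `genotypes` ([GenotypeMatrix-class]),
#'   `images` ([FruitImageSet-class]), `truth` (data.frame with genotypeId,
#'   fsiGenetic, srTarget) and `causalSnps` (ids of the causal SNPs, which
#'   are the first `nCausal` columns).
#' @examples
#' pop <- simulatePopulation(geneticArchitecture(2, 8, rep(0.05, 2)),
#'                           nGenotypes = 4, imagesPerGenotype = 2,
#'                           imageSize = 64, seed = 1)
#' @export
simulatePopulation <- function(arch, nGenotypes, imagesPerGenotype,
                               imageSize = 128L, seed = 1L) {
  stopifnot(is(arch, "GeneticArchitecture"))
  validObject(arch)
  nGenotypes <- assert_count(nGenotypes, "nGenotypes", min = 2L)
  imagesPerGenotype <- assert_count(imagesPerGenotype, "imagesPerGenotype",
                                    min = 1L)
  nSnps <- arch@nCausal + arch@nNeutral
  gid <- sprintf("G%04d", seq_len(nGenotypes))
  sid <- sprintf("SNP%05d", seq_len(nSnps))

  with_seed(seed, {
    dos <- vapply(arch@alleleFreqs,
                  function(p) stats::rbinom(nGenotypes, 2L, p) / 2,
                  numeric(nGenotypes))
    dimnames(dos) <- list(gid, sid)
    fsi_g <- as.numeric(arch@baselineFsi +
      dos[, seq_len(arch@nCausal), drop = FALSE] %*% arch@effectSizes)
    env <- matrix(stats::rnorm(nGenotypes * imagesPerGenotype, 0, arch@envSd),
                  nGenotypes, imagesPerGenotype)
    images <- vector("list", nGenotypes * imagesPerGenotype)
    im_gid <- character(length(images))
    im_iid <- character(length(images))
    k <- 0L
    for (g in seq_len(nGenotypes)) {
      for (r in seq_len(imagesPerGenotype)) {
        k <- k + 1L
        fsi <- min(1.7, max(0.6, fsi_g[g] + env[g, r]))
        images[[k]] <- renderFruit(shapeParams(fsi = fsi, sr = 1),
                                   imageSize = imageSize)
        attributes(images[[k]]) <- list(dim = dim(images[[k]])) # strip extras
        im_gid[k] <- gid[g]
        im_iid[k] <- as.character(r)
      }
    }
    list(genotypes = new("GenotypeMatrix", values = dos),
         images = new("FruitImageSet", images = images,
                      genotypeId = im_gid, imageId = im_iid),
         truth = data.frame(genotypeId = gid, fsiGenetic = fsi_g,
                            srTarget = 1, stringsAsFactors = FALSE),
         causalSnps = sid[seq_len(arch@nCausal)])
  })
}

#' Write a FruitImageSet to disk as PNG files
#'
#' Files are named `<genotypeId>_<imageId>.png`, the naming scheme
#' [loadImageDir()] parses back.
#'
#' @param x a [FruitImageSet-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeFruitImages <- function(x, dir) {
  stopifnot(is(x, "FruitImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s.png", x@genotypeId, x@imageId))
  for (i in seq_along(paths)) png::writePNG(x@images[[i]], paths[i])
  invisible(paths)
}
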