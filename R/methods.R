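#' @rdname genoDraw-accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@values))
#' @rdname genoDraw-accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@values))
#' @rdname genoDraw-accessors
#' @export
setMethod("snpIds", "SNPPanel", function(x) x@snpIds)
#' @rdname genoDraw-accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@values)
#' @rdname genoDraw-accessors
#' @export
setMethod("panelKind", "SNPPanel", function(x) x@kind)

#' @rdname genoDraw-accessors
#' @export
setMethod("genotypeIds", "FruitImageSet", function(x) x@genotypeId)
#' @rdname genoDraw-accessors
#' @export
setMethod("imageIds", "FruitImageSet", function(x) x@imageId)
#' @rdname genoDraw-accessors
#' @export
setMethod("getImage", "FruitImageSet", function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@imageId)
    if (is.na(i)) stop("no image with that id", call. = FALSE)
  }
  x@images[[i]]
})
#' @describeIn genoDraw-accessors number of images in a [FruitImageSet-class].
#' @export
setMethod("length", "FruitImageSet", function(x) length(x@images))

#' Subset a FruitImageSet
#'
#' @param x a [FruitImageSet-class].
#' @param i numeric/logical index over images, or a character vector of
#'   genotype identifiers (all images of those genotypes are kept).
#' @param j,...,drop ignored.
#' @return a [FruitImageSet-class] with the selected images.
#' @export
setMethod("[", "FruitImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- x@genotypeId %in% i
  new("FruitImageSet", images = x@images[i],
      genotypeId = x@genotypeId[i], imageId = x@imageId[i])
})

#' @rdname genoDraw-accessors
#' @export
setMethod("trainGenotypes", "DatasetSplit", function(x) x@trainGenotypes)
#' @rdname genoDraw-accessors
#' @export
setMethod("valGenotypes", "DatasetSplit", function(x) x@valGenotypes)

#' @rdname genoDraw-accessors
#' @export
setMethod("embeddings", "GenotypeEmbeddingTargets", function(x) x@embeddings)
#' @rdname genoDraw-accessors
#' @export
setMethod("decodedImages", "GenotypeEmbeddingTargets",
          function(x) x@decodedImages)
#' @rdname genoDraw-accessors
#' @export
setMethod("genotypeIds", "GenotypeEmbeddingTargets",
          function(x) rownames(x@embeddings))

#' @rdname genoDraw-accessors
#' @export
setMethod("embeddingDim", "AutoencoderSpec", function(x) x@embeddingDim)
#' @rdname genoDraw-accessors
#' @export
setMethod("embeddingDim", "FruitAutoencoder", function(x) x@spec@embeddingDim)
#' @rdname genoDraw-accessors
#' @export
setMethod("lossHistory", "FruitAutoencoder", function(x) x@lossHistory)
#' @rdname genoDraw-accessors
#' @export
setMethod("lossHistory", "EmbeddingPredictor", function(x) x@history)

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs (dosages 0/0.5/1)\n",
              nrow(v), ncol(v)))
})

setMethod("show", "SNPPanel", function(object) {
  cat(sprintf("SNPPanel (%s): %d SNPs (%d targeted + %d random)\n",
              object@kind, length(object@snpIds), object@nTargeted,
              object@nRandom))
})

setMethod("show", "FruitImageSet", function(object) {
  d <- if (length(object@images)) dim(object@images[[1L]]) else c(0, 0, 0)
  cat(sprintf("FruitImageSet: %d images (%dx%dx%d), %d genotypes\n",
              length(object@images), d[1L], d[2L], d[3L],
              length(unique(object@genotypeId))))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation genotypes (%.0f%%)\n",
              length(object@trainGenotypes), length(object@valGenotypes),
              100 * object@trainFraction))
})

setMethod("show", "AutoencoderSpec", function(object) {
  cat(sprintf(
    "AutoencoderSpec: %d conv layers (k=%d, stride=%d, filters %s), dense %s, embedding %d\n",
    object@nConvLayers, object@kernel, object@stride,
    paste(object@filters, collapse = ">"),
    paste(object@denseSizes, collapse = "/"), object@embeddingDim))
})

setMethod("show", "FruitAutoencoder", function(object) {
  cat(sprintf("FruitAutoencoder: %d px input, embedding %d, %s\n",
              object@imageSize, object@spec@embeddingDim,
              if (length(object@lossHistory))
                sprintf("trained %d epochs (%s loss, final %.4g)",
                        length(object@lossHistory), object@loss,
                        object@lossHistory[length(object@lossHistory)])
              else "untrained"))
})

setMethod("show", "EmbeddingPredictor", function(object) {
  cat(sprintf("EmbeddingPredictor: %d SNPs -> %d -> %d, %s\n",
              object@spec@nSnps, object@spec@hiddenUnits,
              object@spec@outputDim,
              if (is.na(object@valMAE)) "untrained"
              else sprintf("trained %d epochs, validation MAE %.4f",
                           nrow(object@history), object@valMAE)))
})

setMethod("show", "GenotypeEmbeddingTargets", function(object) {
  cat(sprintf(
    "GenotypeEmbeddingTargets: %d genotypes x %d embedding dims (%d decoded means)\n",
    nrow(object@embeddings), ncol(object@embeddings),
    length(object@decodedImages)))
})

setMethod("show", "GenoDrawingModel", function(object) {
  cat(sprintf("GenoDrawingModel: %d-SNP %s panel -> %d px image\n",
              length(object@panel@snpIds), object@panel@kind,
              object@imageSize))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  embedding MAE: %.4f\n", object@embeddingMAE))
  cat(sprintf("  FSI MAE: %.4f   SR MAE: %.4f\n", object@fsiMAE,
              object@srMAE))
  cat(sprintf("  null boundary (FSI): %.4f +/- %.4f\n",
              object@nullBoundary[["mean"]], object@nullBoundary[["sd"]]))
  cat(sprintf("  accuracy: %.3f   macro F: %.3f\n", object@accuracy,
              object@fScore))
})
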