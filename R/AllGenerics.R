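#' @name genoDraw-accessors
#' @title Accessors for genoDraw classes
#'
#' @description Small accessor generics: `sampleIds`/`snpIds`/`dosages` for
#' [GenotypeMatrix-class] and [SNPPanel-class]; `genotypeIds`/`imageIds`/
#' `getImage` for [FruitImageSet-class]; `trainGenotypes`/`valGenotypes` for
#' [DatasetSplit-class]; `embeddings`/`decodedImages` for
#' [GenotypeEmbeddingTargets-class]; `embeddingDim`/`lossHistory` for the
#' model classes; `panelKind` for [SNPPanel-class].
#'
#' @param x object to access.
#' @param i image index or image id (for `getImage`).
#' @return The corresponding slot content (identifiers, matrix, list, or
#'   numeric vector).
NULL

#' @rdname genoDraw-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("trainGenotypes", function(x) standardGeneric("trainGenotypes"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("valGenotypes", function(x) standardGeneric("valGenotypes"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("embeddings", function(x) standardGeneric("embeddings"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("decodedImages", function(x) standardGeneric("decodedImages"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname genoDraw-accessors
#' @export
setGeneric("panelKind", function(x) standardGeneric("panelKind"))
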