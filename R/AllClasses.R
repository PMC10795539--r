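#' GenotypeMatrix: SNP dosages for a set of samples
#'
#' Samples-by-SNPs matrix of allele dosages on the \{0, 0.5, 1\} scale
#' (AA, Aa, aa). Row names are sample identifiers, column names SNP
#' identifiers; both must be unique. Missing values are not representable:
#' they must be rejected or explicitly imputed upstream (see
#' [encodeAlleles()]).
#'
#' @slot values numeric matrix, samples x SNPs, entries in \{0, 0.5, 1\}.
#' @seealso [encodeAlleles()], [loadGenotypes()], [selectPanel()]
#' @export
setClass("GenotypeMatrix", representation(values = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("sample (row) and SNP (column) identifiers are required")
  if (anyDuplicated(rownames(v)))
    return("duplicate sample identifiers")
  if (anyDuplicated(colnames(v)))
    return("duplicate SNP identifiers")
  if (!is.numeric(v) || anyNA(v))
    return("dosages must be numeric with no missing values")
  if (!all(v %in% c(0, 0.5, 1)))
    return("dosages must lie in {0, 0.5, 1}")
  TRUE
})

#' SNPPanel: an ordered selection of SNP identifiers
#'
#' A panel is either `targeted` (a fixed, literature-style list), `random`
#' (uniform draw without replacement), or `augmented` (the full targeted core
#' plus random non-targeted fill), mirroring the targeted/random/diluted panel
#' designs used to probe marker relevance.
#'
#' @slot snpIds character, panel members in order, no duplicates.
#' @slot kind one of `"targeted"`, `"random"`, `"augmented"`.
#' @slot nTargeted,nRandom integer composition counts;
#'   `length(snpIds) == nTargeted + nRandom`.
#' @slot seed integer seed used for any random draw (NA for targeted panels).
#' @seealso [selectPanel()]
#' @export
setClass("SNPPanel", representation(
  snpIds = "character", kind = "character",
  nTargeted = "integer", nRandom = "integer", seed = "integer"))

setValidity("SNPPanel", function(object) {
  if (anyDuplicated(object@snpIds)) return("duplicate SNP ids in panel")
  if (!object@kind %in% c("targeted", "random", "augmented"))
    return("kind must be targeted, random or augmented")
  if (length(object@snpIds) != object@nTargeted + object@nRandom)
    return("panel size must equal nTargeted + nRandom")
  if (object@kind == "targeted" && object@nRandom != 0L)
    return("targeted panels cannot contain random SNPs")
  if (object@kind == "random" && object@nTargeted != 0L)
    return("random panels cannot contain targeted SNPs")
  TRUE
})

#' FruitImageSet: a collection of single-fruit RGB images
#'
#' Each image is an H x W x 3 array with intensities in [0, 1], tagged with a
#' genotype identifier and an image identifier (unique within genotype).
#'
#' @slot images list of H x W x 3 numeric arrays in [0, 1].
#' @slot genotypeId character, one genotype id per image.
#' @slot imageId character, one image id per image.
#' @seealso [loadImageDir()], [simulatePopulation()], [writeFruitImages()]
#' @export
setClass("FruitImageSet", representation(
  images = "list", genotypeId = "character", imageId = "character"))

setValidity("FruitImageSet", function(object) {
  n <- length(object@images)
  if (length(object@genotypeId) != n || length(object@imageId) != n)
    return("genotypeId and imageId must have one entry per image")
  if (anyDuplicated(paste(object@genotypeId, object@imageId, sep = "\r")))
    return("duplicate (genotype, image) identifier pairs")
  for (im in object@images) {
    d <- dim(im)
    if (length(d) != 3L || d[3L] != 3L)
      return("every image must be an H x W x 3 array")
    if (anyNA(im) || min(im) < 0 || max(im) > 1)
      return("image intensities must lie in [0, 1]")
  }
  TRUE
})

#' ShapeParams: generative parameters of a synthetic fruit silhouette
#'
#' @slot fsi positive target fruit shape index (height / width).
#' @slot sr positive target shoulder ratio (top width / bottom width at the
#'   measurement insets).
#' @slot lobing radial lobing amplitude in [0, 0.2] (fraction of local width).
#' @slot rotation rotation jitter in degrees.
#' @seealso [shapeParams()], [renderFruit()]
#' @export
setClass("ShapeParams", representation(
  fsi = "numeric", sr = "numeric", lobing = "numeric", rotation = "numeric"))

setValidity("ShapeParams", function(object) {
  if (object@fsi <= 0) return("fsi must be positive")
  if (object@sr <= 0) return("sr must be positive")
  if (object@lobing < 0 || object@lobing > 0.2)
    return("lobing amplitude must lie in [0, 0.2]")
  TRUE
})

#' GeneticArchitecture: additive genetics of the simulated population
#'
#' The genotype-to-phenotype map is purely additive on the fruit shape index:
#' per-genotype FSI = `baselineFsi + sum(effectSizes * dosage)`, and each
#' rendered image adds independent `N(0, envSd)` environmental noise to it.
#'
#' @slot nCausal,nNeutral counts of causal and neutral SNPs.
#' @slot effectSizes numeric of length `nCausal`; additive effect of one unit
#'   of dosage (0/0.5/1 scale) on the FSI.
#' @slot baselineFsi baseline FSI of the zero-dosage genotype.
#' @slot envSd non-negative within-genotype (per image) FSI standard deviation.
#' @slot alleleFreqs numeric in (0, 1), recycled to `nCausal + nNeutral`;
#'   frequency of the dosage-increasing allele, Hardy-Weinberg sampling.
#' @seealso [geneticArchitecture()], [simulatePopulation()]
#' @export
setClass("GeneticArchitecture", representation(
  nCausal = "integer", nNeutral = "integer", effectSizes = "numeric",
  baselineFsi = "numeric", envSd = "numeric", alleleFreqs = "numeric"))

setValidity("GeneticArchitecture", function(object) {
  if (object@nCausal + object@nNeutral < 1L)
    return("at least one SNP is required")
  if (length(object@effectSizes) != object@nCausal)
    return("effectSizes must have one entry per causal SNP")
  if (object@envSd < 0) return("envSd must be non-negative")
  if (any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
    return("allele frequencies must lie strictly in (0, 1)")
  if (object@baselineFsi <= 0) return("baselineFsi must be positive")
  TRUE
})

#' DatasetSplit: genotype-level train/validation partition
#'
#' The split unit is the genotype: all images of a genotype land on one side,
#' and within each shape stratum the genotype count is divided as close to
#' `trainFraction` as integer rounding allows.
#'
#' @slot trainGenotypes,valGenotypes character vectors, disjoint.
#' @slot trainFraction real in (0, 1).
#' @seealso [stratifiedSplit()]
#' @export
setClass("DatasetSplit", representation(
  trainGenotypes = "character", valGenotypes = "character",
  trainFraction = "numeric"))

setValidity("DatasetSplit", function(object) {
  if (length(intersect(object@trainGenotypes, object@valGenotypes)) > 0L)
    return("train and validation genotype sets must be disjoint")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  TRUE
})

#' AutoencoderSpec: architecture of the convolutional autoencoder
#'
#' The encoder applies `nConvLayers` stride-2 3x3 convolutions with
#' rectified-linear activation and a non-decreasing filter ladder, flattens
#' the final feature map, passes it through three leaky-rectified dense
#' layers, and ends in an `embeddingDim`-unit dense layer with sigmoid
#' activation so every embedding coordinate lies in [0, 1]. The decoder
#' mirrors the encoder layer-for-layer and ends in a sigmoid output layer.
#'
#' @slot nConvLayers integer count of stride-2 convolutions (default 6).
#' @slot kernel convolution kernel size in pixels (default 3).
#' @slot stride convolution stride (default 2).
#' @slot filters integer vector of length `nConvLayers`, non-decreasing.
#' @slot denseSizes integer vector of dense-layer widths
#'   (default 8192, 4096, 2048).
#' @slot embeddingDim width of the sigmoid bottleneck (default 64).
#' @seealso [autoencoderSpec()], [deskAutoencoderSpec()], [buildAutoencoder()]
#' @export
setClass("AutoencoderSpec", representation(
  nConvLayers = "integer", kernel = "integer", stride = "integer",
  filters = "integer", denseSizes = "integer", embeddingDim = "integer"))

setValidity("AutoencoderSpec", function(object) {
  if (object@embeddingDim < 1L) return("embeddingDim must be >= 1")
  if (length(object@filters) != object@nConvLayers)
    return("filters must have one entry per convolution layer")
  if (is.unsorted(object@filters))
    return("filters must be non-decreasing")
  if (length(object@denseSizes) < 1L) return("at least one dense layer")
  TRUE
})

#' FruitAutoencoder: a (possibly trained) convolutional autoencoder
#'
#' @slot spec the [AutoencoderSpec-class] the network was built from.
#' @slot imageSize input height/width in pixels.
#' @slot encoder,decoder internal layer stacks.
#' @slot lossHistory per-epoch mean training loss (empty until trained).
#' @slot loss loss name used in training ("" until trained).
#' @slot seed seed used for weight initialisation.
#' @seealso [buildAutoencoder()], [trainAutoencoder()], [encodeImages()]
#' @export
setClass("FruitAutoencoder", representation(
  spec = "AutoencoderSpec", imageSize = "integer", encoder = "list",
  decoder = "list", lossHistory = "numeric", loss = "character",
  seed = "integer"))

#' PredictorSpec: architecture and training policy of the embedding predictor
#'
#' A two-layer dense network (`nSnps -> hiddenUnits -> outputDim`, sigmoid
#' activations on both layers) trained with mean absolute error under SGD,
#' a reduce-on-plateau learning-rate scheduler and an early stopper watching
#' the validation MAE.
#'
#' @slot nSnps input width (panel size).
#' @slot hiddenUnits hidden-layer width (default 300).
#' @slot outputDim output width; must equal the autoencoder embedding
#'   dimension it will be paired with (default 64).
#' @slot maxEpochs training-epoch cap (default 1000).
#' @slot learningRate initial SGD learning rate (default 0.05).
#' @slot schedulerFactor,schedulerPatience reduce-on-plateau policy
#'   (default 0.5, 10).
#' @slot earlyStopPatience,earlyStopMinDelta early-stopping policy
#'   (default 25, 1e-4).
#' @seealso [predictorSpec()], [buildPredictor()], [trainPredictor()]
#' @export
setClass("PredictorSpec", representation(
  nSnps = "integer", hiddenUnits = "integer", outputDim = "integer",
  maxEpochs = "integer", learningRate = "numeric",
  schedulerFactor = "numeric", schedulerPatience = "integer",
  earlyStopPatience = "integer", earlyStopMinDelta = "numeric"))

setValidity("PredictorSpec", function(object) {
  if (object@nSnps < 1L) return("nSnps must be >= 1")
  if (object@outputDim < 1L) return("outputDim must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' EmbeddingPredictor: SNP-dosage to embedding regression model
#'
#' @slot spec the [PredictorSpec-class] it was built from.
#' @slot layers internal layer stack.
#' @slot snpIds SNP identifiers the input columns correspond to (set at
#'   training time; empty before).
#' @slot history data.frame with one row per trained epoch: epoch, trainMAE,
#'   valMAE, learningRate.
#' @slot valMAE final validation MAE (NA until trained).
#' @seealso [buildPredictor()], [trainPredictor()]
#' @export
setClass("EmbeddingPredictor", representation(
  spec = "PredictorSpec", layers = "list", snpIds = "character",
  history = "data.frame", valMAE = "numeric"))

#' GenotypeEmbeddingTargets: per-genotype mean embeddings and decoded means
#'
#' The element-wise arithmetic mean of each genotype's image embeddings
#' (the regression target for the embedding predictor) and, optionally, the
#' image obtained by decoding that mean vector.
#'
#' @slot embeddings genotypes x embeddingDim numeric matrix; row names are
#'   genotype identifiers.
#' @slot decodedImages named list of decoded mean images (may be empty).
#' @seealso [buildGenotypeTargets()]
#' @export
setClass("GenotypeEmbeddingTargets", representation(
  embeddings = "matrix", decodedImages = "list"))

setValidity("GenotypeEmbeddingTargets", function(object) {
  if (is.null(rownames(object@embeddings)))
    return("embedding rows must be named by genotype")
  if (anyDuplicated(rownames(object@embeddings)))
    return("duplicate genotype ids")
  if (length(object@decodedImages) &&
      !all(names(object@decodedImages) %in% rownames(object@embeddings)))
    return("decoded images must correspond to target genotypes")
  TRUE
})

#' GenoDrawingModel: the assembled SNP-to-image model
#'
#' A trained embedding predictor attached to the decoder of a trained
#' autoencoder. Assembly performs no weight updates; drawing a genotype is
#' the exact composition `decode(predict(dosages))`.
#'
#' @slot predictor trained [EmbeddingPredictor-class].
#' @slot decoder decoder layer stack taken from a trained autoencoder.
#' @slot imageSize output image size in pixels.
#' @slot panel the [SNPPanel-class] the predictor was trained on.
#' @seealso [assembleGenoDrawing()], [drawGenotype()]
#' @export
setClass("GenoDrawingModel", representation(
  predictor = "EmbeddingPredictor", decoder = "list", imageSize = "integer",
  panel = "SNPPanel"))

#' EvalReport: evaluation summary for an SNP-to-image model
#'
#' @slot embeddingMAE mean absolute error between predicted and target
#'   embeddings.
#' @slot fsiMAE,srMAE mean absolute error of the fruit shape index and
#'   shoulder ratio of drawn images against the decoded per-genotype means.
#' @slot nullBoundary named numeric (mean, sd): the resampling null threshold
#'   for the FSI MAE.
#' @slot wasserstein named numeric of 1-D Wasserstein distances between
#'   predicted/decoded/original FSI distributions.
#' @slot confusion 5 x 5 shape-category confusion matrix (true in rows).
#' @slot accuracy,fScore classification accuracy and macro F score.
#' @slot config list echoing thresholds, seeds and panel composition.
#' @seealso [evaluateGenoDrawing()]
#' @export
setClass("EvalReport", representation(
  embeddingMAE = "numeric", fsiMAE = "numeric", srMAE = "numeric",
  nullBoundary = "numeric", wasserstein = "numeric", confusion = "matrix",
  accuracy = "numeric", fScore = "numeric", config = "list"))
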