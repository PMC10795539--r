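# Convolutional autoencoder: architecture builders, training, encoding,
# decoding, and per-genotype mean-embedding targets.

#' Default autoencoder architecture
#'
#' Six stride-2 3x3 convolutions with a rising filter ladder from 16 to 128,
#' three leaky-rectified dense layers of 8192, 4096 and 2048 units, and a
#' 64-unit sigmoid bottleneck; the decoder mirrors the encoder and ends in a
#' sigmoid output layer. Intended for 300 px inputs.
#'
#' @param nConvLayers,kernel,stride,filters,denseSizes,embeddingDim
#'   architecture fields; see [AutoencoderSpec-class].
#' @return an [AutoencoderSpec-class].
#' @examples
#' autoencoderSpec()
#' @export
autoencoderSpec <- function(nConvLayers = 6L, kernel = 3L, stride = 2L,
                            filters = c(16L, 32L, 48L, 64L, 96L, 128L),
                            denseSizes = c(8192L, 4096L, 2048L),
                            embeddingDim = 64L) {
  new("AutoencoderSpec", nConvLayers = assert_count(nConvLayers, "nConvLayers", 1L),
      kernel = assert_count(kernel, "kernel", 1L),
      stride = assert_count(stride, "stride", 1L),
      filters = as.integer(filters), denseSizes = as.integer(denseSizes),
      embeddingDim = assert_count(embeddingDim, "embeddingDim", 1L))
}

#' Desk-scale autoencoder architecture
#'
#' A reduced profile for CPU-scale runs: 64 px inputs, four stride-2
#' convolutions (filters 8 to 64), dense layers 1024/512/256, and the same
#' 64-value sigmoid bottleneck as the full architecture.
#'
#' @param embeddingDim bottleneck width.
#' @return an [AutoencoderSpec-class].
#' @export
deskAutoencoderSpec <- function(embeddingDim = 64L) {
  autoencoderSpec(nConvLayers = 4L, filters = c(8L, 16L, 32L, 64L),
                  denseSizes = c(1024L, 512L, 256L),
                  embeddingDim = embeddingDim)
}

#' Build an (untrained) convolutional autoencoder
#'
#' The encoder maps an `imageSize x imageSize x 3` image through the spec's
#' convolution stack, flattens the final feature map into the first dense
#' layer, and ends in the sigmoid bottleneck, so every embedding coordinate
#' lies in [0, 1]. The decoder mirrors the encoder layer-for-layer
#' (dense stack reversed, transposed convolutions recovering each encoder
#' map size exactly) and ends in a sigmoid output, so decoded intensities lie
#' in [0, 1].
#'
#' @param spec an [AutoencoderSpec-class].
#' @param imageSize input side in pixels; must survive `nConvLayers`
#'   stride-reductions (an error states the failing dimension otherwise).
#' @param seed integer seed for weight initialisation.
#' @return an untrained [FruitAutoencoder-class].
#' @examples
#' ae <- buildAutoencoder(deskAutoencoderSpec(), imageSize = 64)
#' @export
buildAutoencoder <- function(spec, imageSize = 300L, seed = 1L) {
  stopifnot(is(spec, "AutoencoderSpec"))
  validObject(spec)
  imageSize <- assert_count(imageSize, "imageSize", min = 8L)
  k <- spec@kernel; st <- spec@stride; pad <- (spec@kernel - 1L) %/% 2L

  sizes <- integer(spec@nConvLayers + 1L)
  sizes[1L] <- imageSize
  for (i in seq_len(spec@nConvLayers)) {
    nxt <- nn_conv_out(sizes[i], k, st, pad)
    if (nxt < 2L)
      stop(sprintf(
        "imageSize %d incompatible with spec: convolution %d reduces a %d-px map below 2 px",
        imageSize, i, sizes[i]), call. = FALSE)
    sizes[i + 1L] <- nxt
  }
  chans <- c(3L, spec@filters)
  flat <- sizes[spec@nConvLayers + 1L]^2 * spec@filters[spec@nConvLayers]

  with_seed(seed, {
    enc <- list()
    for (i in seq_len(spec@nConvLayers))
      enc <- c(enc, list(nn_conv(c(sizes[i], sizes[i], chans[i]),
                                 chans[i + 1L], k, st, pad, act = "relu")))
    enc <- c(enc, list(nn_flatten(c(sizes[spec@nConvLayers + 1L],
                                    sizes[spec@nConvLayers + 1L],
                                    spec@filters[spec@nConvLayers]))))
    widths <- c(flat, spec@denseSizes)
    for (i in seq_len(length(spec@denseSizes)))
      enc <- c(enc, list(nn_dense(widths[i], widths[i + 1L], act = "lrelu")))
    enc <- c(enc, list(nn_dense(widths[length(widths)], spec@embeddingDim,
                                act = "sigmoid")))

    dec <- list()
    dwidths <- c(spec@embeddingDim, rev(spec@denseSizes), flat)
    for (i in seq_len(length(dwidths) - 1L))
      dec <- c(dec, list(nn_dense(dwidths[i], dwidths[i + 1L], act = "lrelu")))
    last_map <- sizes[spec@nConvLayers + 1L]
    dec <- c(dec, list(nn_reshape(c(last_map, last_map,
                                    spec@filters[spec@nConvLayers]))))
    for (i in rev(seq_len(spec@nConvLayers))) {
      act <- if (i == 1L) "sigmoid" else "relu"
      dec <- c(dec, list(nn_convt(c(sizes[i + 1L], sizes[i + 1L],
                                    chans[i + 1L]),
                                  chans[i], k, st, pad,
                                  out_hw = c(sizes[i], sizes[i]),
                                  act = act)))
    }
    new("FruitAutoencoder", spec = spec, imageSize = imageSize,
        encoder = enc, decoder = dec, lossHistory = numeric(0), loss = "",
        seed = as.integer(seed))
  })
}

#' Train the autoencoder on a set of images
#'
#' Mini-batch stochastic gradient descent with momentum on the selected
#' reconstruction loss. `loss = "perceptual"` is an explicit error: it
#' requires a pretrained feature-extractor network whose weights are not
#' bundled; `"mse"` and `"ssim"` are the self-contained choices.
#'
#' @param ae a [FruitAutoencoder-class] (untrained or to be trained further).
#' @param images a [FruitImageSet-class], list of arrays, or [H, W, 3, N]
#'   array, all matching the model's `imageSize`.
#' @param loss `"mse"`, `"ssim"` or `"perceptual"`.
#' @param epochs training epochs (default 35).
#' @param learningRate,momentum,batchSize SGD settings.
#' @param seed integer seed controlling shuffling.
#' @param verbose print the per-epoch loss?
#' @return the trained [FruitAutoencoder-class]; `lossHistory(.)` has one
#'   mean training loss per epoch.
#' @export
trainAutoencoder <- function(ae, images, loss = c("mse", "ssim", "perceptual"),
                             epochs = 35L, learningRate = 0.1,
                             momentum = 0.9, batchSize = 8L, seed = 1L,
                             verbose = FALSE) {
  stopifnot(is(ae, "FruitAutoencoder"))
  loss <- match.arg(loss)
  loss_fn <- nn_loss(loss)
  epochs <- assert_count(epochs, "epochs", min = 1L)
  x <- if (is.array(images) && length(dim(images)) == 4L) images
       else stack_images(images)
  if (dim(x)[1L] != ae@imageSize || dim(x)[2L] != ae@imageSize)
    stop(sprintf("images are %dx%d but the model expects %dx%d",
                 dim(x)[1L], dim(x)[2L], ae@imageSize, ae@imageSize),
         call. = FALSE)
  n <- dim(x)[4L]
  if (n < 1L) stop("at least one training image is required", call. = FALSE)

  layers <- c(ae@encoder, ae@decoder)
  state <- nn_sgd_init(layers)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = batchSize)) {
        idx <- ord[b0:min(b0 + batchSize - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- nn_forward(layers, xb, training = TRUE)
        l <- loss_fn(fw$out, xb)
        grads <- nn_backward(layers, fw$caches, l$grad)
        upd <- nn_sgd_step(layers, grads, state, learningRate, momentum)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + l$value
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose)
        message(sprintf("epoch %d/%d: %s loss %.5f", ep, epochs, loss,
                        history[ep]))
    }
  })
  n_enc <- length(ae@encoder)
  ae@encoder <- layers[seq_len(n_enc)]
  ae@decoder <- layers[-seq_len(n_enc)]
  ae@lossHistory <- c(ae@lossHistory, history)
  ae@loss <- loss
  ae
}

#' Encode images into embedding vectors
#'
#' Deterministic inference pass through the encoder; identical images yield
#' identical embeddings.
#'
#' @param ae a [FruitAutoencoder-class].
#' @param images a [FruitImageSet-class], list of arrays, or [H, W, 3, N]
#'   array.
#' @return an N x embeddingDim matrix in [0, 1]; when a [FruitImageSet-class]
#'   is supplied, rows are named by image and an attribute `genotypeId`
#'   carries the genotype of each row.
#' @export
encodeImages <- function(ae, images) {
  stopifnot(is(ae, "FruitAutoencoder"))
  x <- if (is.array(images) && length(dim(images)) == 4L) images
       else stack_images(images)
  if (dim(x)[1L] != ae@imageSize || dim(x)[2L] != ae@imageSize)
    stop(sprintf("images are %dx%d but the encoder expects %dx%d",
                 dim(x)[1L], dim(x)[2L], ae@imageSize, ae@imageSize),
         call. = FALSE)
  emb <- t(nn_forward(ae@encoder, x)$out)
  if (is(images, "FruitImageSet")) {
    rownames(emb) <- paste(images@genotypeId, images@imageId, sep = "_")
    attr(emb, "genotypeId") <- images@genotypeId
  }
  emb
}

#' Decode embedding vectors into images
#'
#' @param ae a [FruitAutoencoder-class].
#' @param embeddings an N x embeddingDim matrix (or a single vector).
#' @return an [H, W, 3, N] array of decoded images with intensities in
#'   [0, 1].
#' @export
decodeEmbeddings <- function(ae, embeddings) {
  stopifnot(is(ae, "FruitAutoencoder"))
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  if (ncol(embeddings) != ae@spec@embeddingDim)
    stop(sprintf("embeddings have %d dims but the decoder expects %d",
                 ncol(embeddings), ae@spec@embeddingDim), call. = FALSE)
  nn_forward(ae@decoder, t(embeddings))$out
}

#' Per-genotype mean-embedding targets
#'
#' Groups image embeddings by genotype and takes the element-wise arithmetic
#' mean: that mean vector is the regression target for the embedding
#' predictor, and (optionally) its decoding is the genotype's mean image.
#'
#' @param embeddings N x embeddingDim matrix of per-image embeddings.
#' @param genotypes character vector: genotype of each embedding row. A
#'   factor with an empty level (a genotype with zero images) is an error.
#' @param ae optional [FruitAutoencoder-class]; when supplied, each mean
#'   vector is decoded into the genotype's mean image.
#' @return a [GenotypeEmbeddingTargets-class].
#' @export
buildGenotypeTargets <- function(embeddings, genotypes = NULL, ae = NULL) {
  if (is.null(genotypes)) genotypes <- attr(embeddings, "genotypeId")
  if (is.null(genotypes))
    stop("genotypes must be supplied (or attached to the embeddings)",
         call. = FALSE)
  if (length(genotypes) != nrow(embeddings))
    stop("one genotype per embedding row is required", call. = FALSE)
  f <- if (is.factor(genotypes)) genotypes else factor(genotypes)
  if (any(table(f) == 0L))
    stop("genotype(s) with zero images: ",
         paste(names(which(table(f) == 0L)), collapse = ", "), call. = FALSE)
  counts <- table(f)
  means <- rowsum(as.matrix(embeddings), f)
  means <- means / as.vector(counts[rownames(means)])
  decoded <- list()
  if (!is.null(ae)) {
    imgs <- decodeEmbeddings(ae, means)
    decoded <- lapply(seq_len(nrow(means)), function(i) imgs[, , , i])
    names(decoded) <- rownames(means)
  }
  new("GenotypeEmbeddingTargets", embeddings = unname_attr(means),
      decodedImages = decoded)
}

# rowsum keeps dimnames; make sure only rownames survive
unname_attr <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- NULL
  m
}

#' Save / load genoDraw model objects
#'
#' Single-file checkpoints (RDS) with the architecture spec embedded in the
#' object itself.
#'
#' @param object a [FruitAutoencoder-class], [EmbeddingPredictor-class] or
#'   [GenoDrawingModel-class].
#' @param path checkpoint path.
#' @return `saveModel` returns `path` invisibly; `loadModel` the restored
#'   object.
#' @export
saveModel <- function(object, path) {
  stopifnot(is(object, "FruitAutoencoder") ||
            is(object, "EmbeddingPredictor") ||
            is(object, "GenoDrawingModel"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!(is(obj, "FruitAutoencoder") || is(obj, "EmbeddingPredictor") ||
        is(obj, "GenoDrawingModel")))
    stop("not a genoDraw model checkpoint", call. = FALSE)
  obj
}
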