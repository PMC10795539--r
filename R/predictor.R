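# SNP-to-embedding predictor and the assembled SNP-to-image model.

#' Embedding-predictor architecture and training policy
#'
#' @param nSnps input width (panel size).
#' @param hiddenUnits hidden-layer width.
#' @param outputDim output width; must equal the paired autoencoder's
#'   embedding dimension.
#' @param maxEpochs epoch cap.
#' @param learningRate initial SGD learning rate.
#' @param schedulerFactor,schedulerPatience reduce-on-plateau policy: when
#'   the watched MAE fails to improve by `earlyStopMinDelta` for
#'   `schedulerPatience` epochs, the learning rate is multiplied by
#'   `schedulerFactor`.
#' @param earlyStopPatience,earlyStopMinDelta early stopping: training halts
#'   when the watched MAE fails to improve by `earlyStopMinDelta` for
#'   `earlyStopPatience` epochs; the best weights are restored.
#' @return a [PredictorSpec-class].
#' @examples
#' predictorSpec(150)
#' @export
predictorSpec <- function(nSnps, hiddenUnits = 300L, outputDim = 64L,
                          maxEpochs = 1000L, learningRate = 0.05,
                          schedulerFactor = 0.5, schedulerPatience = 10L,
                          earlyStopPatience = 25L,
                          earlyStopMinDelta = 1e-4) {
  new("PredictorSpec", nSnps = assert_count(nSnps, "nSnps", 1L),
      hiddenUnits = assert_count(hiddenUnits, "hiddenUnits", 1L),
      outputDim = assert_count(outputDim, "outputDim", 1L),
      maxEpochs = assert_count(maxEpochs, "maxEpochs", 1L),
      learningRate = assert_scalar_number(learningRate, "learningRate"),
      schedulerFactor = assert_scalar_number(schedulerFactor,
                                             "schedulerFactor", 0, 1),
      schedulerPatience = assert_count(schedulerPatience,
                                       "schedulerPatience", 1L),
      earlyStopPatience = assert_count(earlyStopPatience,
                                       "earlyStopPatience", 1L),
      earlyStopMinDelta = assert_scalar_number(earlyStopMinDelta,
                                               "earlyStopMinDelta", 0))
}

#' Build an (untrained) embedding predictor
#'
#' A two-layer dense network `nSnps -> hiddenUnits -> outputDim` with sigmoid
#' activation on both layers, so outputs lie in (0, 1) and feed the decoder's
#' embedding input directly.
#'
#' @param spec a [PredictorSpec-class].
#' @param seed integer seed for weight initialisation.
#' @return an [EmbeddingPredictor-class].
#' @export
buildPredictor <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PredictorSpec"))
  validObject(spec)
  with_seed(seed, {
    layers <- list(nn_dense(spec@nSnps, spec@hiddenUnits, act = "sigmoid"),
                   nn_dense(spec@hiddenUnits, spec@outputDim,
                            act = "sigmoid"))
    new("EmbeddingPredictor", spec = spec, layers = layers,
        snpIds = character(0),
        history = data.frame(epoch = integer(0), trainMAE = numeric(0),
                             valMAE = numeric(0), learningRate = numeric(0)),
        valMAE = NA_real_)
  })
}

#' Number of trainable parameters of a predictor
#'
#' @param predictor an [EmbeddingPredictor-class].
#' @return integer parameter count (weights plus biases).
#' @export
nParameters <- function(predictor) {
  stopifnot(is(predictor, "EmbeddingPredictor"))
  as.integer(nn_n_params(predictor@layers))
}

#' Predict embeddings from SNP dosages
#'
#' @param predictor a (trained) [EmbeddingPredictor-class].
#' @param x genotypes x SNPs dosage matrix whose columns match the
#'   predictor's input width (and, if set, its `snpIds` order), or a
#'   [GenotypeMatrix-class] from which the trained panel columns are taken.
#' @return genotypes x outputDim matrix in (0, 1).
#' @export
predictEmbeddings <- function(predictor, x) {
  stopifnot(is(predictor, "EmbeddingPredictor"))
  if (is(x, "GenotypeMatrix")) {
    if (!length(predictor@snpIds))
      stop("predictor has no panel; supply a plain dosage matrix",
           call. = FALSE)
    missing <- setdiff(predictor@snpIds, colnames(x@values))
    if (length(missing))
      stop("genotype matrix lacks panel SNP(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x@values[, predictor@snpIds, drop = FALSE]
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != predictor@spec@nSnps)
    stop(sprintf("input has %d SNPs but the predictor expects %d", ncol(x),
                 predictor@spec@nSnps), call. = FALSE)
  out <- t(nn_forward(predictor@layers, t(x))$out)
  rownames(out) <- rownames(x)
  out
}

#' Train the embedding predictor on per-genotype mean-embedding targets
#'
#' Mini-batch SGD on the mean absolute error between predicted and target
#' embedding vectors, with a reduce-on-plateau learning-rate scheduler and an
#' early stopper watching the validation MAE (the training MAE when no
#' validation genotypes are given). The best-scoring weights are restored at
#' the end.
#'
#' @param predictor an [EmbeddingPredictor-class] built with `nSnps` equal to
#'   the panel size.
#' @param genotypes a [GenotypeMatrix-class] containing every target
#'   genotype (an absent genotype is an error naming it).
#' @param panel an [SNPPanel-class] (or character vector of SNP ids) whose
#'   columns form the predictor input.
#' @param targets a [GenotypeEmbeddingTargets-class] (or a genotype x
#'   embeddingDim matrix with genotype row names) holding train and
#'   validation targets.
#' @param valGenotypes character vector of validation genotype ids (their
#'   targets are watched, never trained on).
#' @param batchSize mini-batch size.
#' @param seed integer seed controlling shuffling.
#' @param verbose print per-epoch progress?
#' @return the trained [EmbeddingPredictor-class]; `lossHistory(.)` holds the
#'   per-epoch train/validation MAE and learning rate, `.@valMAE` the final
#'   (best) watched MAE.
#' @export
trainPredictor <- function(predictor, genotypes, panel, targets,
                           valGenotypes = character(0), batchSize = 16L,
                           seed = 1L, verbose = FALSE) {
  stopifnot(is(predictor, "EmbeddingPredictor"),
            is(genotypes, "GenotypeMatrix"))
  snp_ids <- if (is(panel, "SNPPanel")) panel@snpIds else as.character(panel)
  if (length(snp_ids) != predictor@spec@nSnps)
    stop(sprintf("panel has %d SNPs but the predictor expects %d",
                 length(snp_ids), predictor@spec@nSnps), call. = FALSE)
  tgt <- if (is(targets, "GenotypeEmbeddingTargets")) targets@embeddings
         else as.matrix(targets)
  if (ncol(tgt) != predictor@spec@outputDim)
    stop(sprintf("targets have %d dims but the predictor outputs %d",
                 ncol(tgt), predictor@spec@outputDim), call. = FALSE)
  gids <- rownames(tgt)
  absent <- setdiff(gids, rownames(genotypes@values))
  if (length(absent))
    stop("target genotype(s) absent from the genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  bad_panel <- setdiff(snp_ids, colnames(genotypes@values))
  if (length(bad_panel))
    stop("panel SNP(s) absent from the genotype matrix: ",
         paste(bad_panel, collapse = ", "), call. = FALSE)

  train_g <- setdiff(gids, valGenotypes)
  val_g <- intersect(valGenotypes, gids)
  x_tr <- t(genotypes@values[train_g, snp_ids, drop = FALSE])  # snps x n
  y_tr <- t(tgt[train_g, , drop = FALSE])                      # dim x n
  x_va <- t(genotypes@values[val_g, snp_ids, drop = FALSE])
  y_va <- t(tgt[val_g, , drop = FALSE])

  spec <- predictor@spec
  layers <- predictor@layers
  state <- nn_sgd_init(layers)
  lr <- spec@learningRate
  n <- length(train_g)
  best <- Inf
  best_layers <- layers
  since_sched <- 0L
  since_stop <- 0L
  hist <- vector("list", spec@maxEpochs)

  mae_of <- function(layers, x, y) {
    if (!ncol(x)) return(NA_real_)
    mean(abs(nn_forward(layers, x)$out - y))
  }

  with_seed(seed, {
    for (ep in seq_len(spec@maxEpochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batchSize)) {
        idx <- ord[b0:min(b0 + batchSize - 1L, n)]
        xb <- x_tr[, idx, drop = FALSE]
        yb <- y_tr[, idx, drop = FALSE]
        fw <- nn_forward(layers, xb, training = TRUE)
        g <- sign(fw$out - yb) / length(yb)
        grads <- nn_backward(layers, fw$caches, g)
        upd <- nn_sgd_step(layers, grads, state, lr, 0.9)
        layers <- upd$layers
        state <- upd$state
      }
      tr_mae <- mae_of(layers, x_tr, y_tr)
      va_mae <- mae_of(layers, x_va, y_va)
      watched <- if (is.na(va_mae)) tr_mae else va_mae
      hist[[ep]] <- c(epoch = ep, trainMAE = tr_mae, valMAE = va_mae,
                      learningRate = lr)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f lr %.4g", ep, tr_mae,
                        va_mae, lr))
      if (watched < best - spec@earlyStopMinDelta) {
        best <- watched
        best_layers <- layers
        since_sched <- 0L
        since_stop <- 0L
      } else {
        since_sched <- since_sched + 1L
        since_stop <- since_stop + 1L
        if (since_sched >= spec@schedulerPatience) {
          lr <- lr * spec@schedulerFactor
          since_sched <- 0L
        }
        if (since_stop >= spec@earlyStopPatience) break
      }
    }
  })
  predictor@layers <- best_layers
  predictor@snpIds <- snp_ids
  predictor@history <- as.data.frame(do.call(rbind,
                                             hist[!vapply(hist, is.null,
                                                          logical(1))]))
  predictor@valMAE <- best
  predictor
}

#' Assemble the SNP-to-image model
#'
#' Attaches a trained embedding predictor to the decoder of a trained
#' autoencoder. No weights are updated: the assembled model is the exact
#' functional composition `decode(predict(dosages))`.
#'
#' @param predictor a trained [EmbeddingPredictor-class].
#' @param ae the trained [FruitAutoencoder-class] whose decoder is reused.
#' @param panel the [SNPPanel-class] the predictor was trained on.
#' @return a [GenoDrawingModel-class].
#' @export
assembleGenoDrawing <- function(predictor, ae, panel) {
  stopifnot(is(predictor, "EmbeddingPredictor"), is(ae, "FruitAutoencoder"),
            is(panel, "SNPPanel"))
  if (predictor@spec@outputDim != ae@spec@embeddingDim)
    stop(sprintf(
      "predictor outputs %d values but the decoder expects %d embeddings",
      predictor@spec@outputDim, ae@spec@embeddingDim), call. = FALSE)
  if (length(panel@snpIds) != predictor@spec@nSnps)
    stop("panel size does not match the predictor input width",
         call. = FALSE)
  new("GenoDrawingModel", predictor = predictor, decoder = ae@decoder,
      imageSize = ae@imageSize, panel = panel)
}

#' Draw the predicted fruit image for a genotype
#'
#' Deterministic inference: the same dosages always produce the same image.
#'
#' @param model a [GenoDrawingModel-class].
#' @param dosages a named numeric vector (or single-row matrix) of dosages in
#'   \{0, 0.5, 1\} covering every panel SNP (missing SNPs are an error
#'   listing them), or a [GenotypeMatrix-class] row selected by
#'   `genotypeId`.
#' @param genotypeId sample id used when `dosages` is a
#'   [GenotypeMatrix-class].
#' @return an `imageSize x imageSize x 3` array in [0, 1].
#' @export
drawGenotype <- function(model, dosages, genotypeId = NULL) {
  stopifnot(is(model, "GenoDrawingModel"))
  ids <- model@panel@snpIds
  if (is(dosages, "GenotypeMatrix")) {
    if (is.null(genotypeId))
      stop("genotypeId is required with a GenotypeMatrix", call. = FALSE)
    dosages <- dosages@values[genotypeId, ]
  }
  if (!is.null(dim(dosages))) dosages <- dosages[1L, ]
  missing <- setdiff(ids, names(dosages))
  if (length(missing))
    stop("dosages missing panel SNP(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- dosages[ids]
  if (!all(v %in% c(0, 0.5, 1)))
    stop("dosages must lie in {0, 0.5, 1}", call. = FALSE)
  emb <- nn_forward(model@predictor@layers, matrix(v, ncol = 1L))$out
  img <- nn_forward(model@decoder, emb)$out
  array(img, dim(img)[1:3])
}
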