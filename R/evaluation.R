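# Evaluation battery: MAE comparisons, the resampling null threshold,
# Wasserstein distances, shape-class confusion, model batteries and the
# panel-size ladder.

#' Mean absolute error between two embedding matrices
#'
#' @param predicted,target numeric matrices (or vectors) of identical shape.
#' @return mean of `abs(predicted - target)` over every entry.
#' @export
embeddingMAE <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target))
    stop("predicted and target must have identical shapes", call. = FALSE)
  mean(abs(predicted - target))
}

#' Resampling null threshold for a shape-metric MAE
#'
#' Estimates the MAE level a predictor would reach by merely sampling each
#' genotype's own phenotype distribution: for each of `nDatasets` replicates,
#' one value per genotype is drawn from Normal(mu_g, sd_g) and the MAE of the
#' drawn values against the per-genotype means is computed. A model MAE below
#' `mean(replicate MAEs)` indicates the predictions are not random draws from
#' the observed distributions.
#'
#' @param stats data.frame with columns `genotypeId`, `mu` (per-genotype
#'   metric mean) and `sigma` (per-genotype metric standard deviation,
#'   non-negative).
#' @param nDatasets number of resampled datasets (default 10000).
#' @param seed integer seed.
#' @return named numeric: `mean` and `sd` of the replicate MAEs.
#' @export
nullThreshold <- function(stats, nDatasets = 10000L, seed = 1L) {
  if (!all(c("mu", "sigma") %in% names(stats)) || nrow(stats) == 0L)
    stop("stats must be a nonempty data.frame with mu and sigma columns",
         call. = FALSE)
  if (any(stats$sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  nDatasets <- assert_count(nDatasets, "nDatasets", min = 1L)
  g <- nrow(stats)
  maes <- with_seed(seed, {
    dev <- matrix(stats::rnorm(g * nDatasets, 0, stats$sigma), g, nDatasets)
    colMeans(abs(dev))
  })
  c(mean = mean(maes), sd = stats::sd(maes))
}

#' Per-genotype mean and standard deviation of a shape metric
#'
#' @param shapes a data.frame as returned by [measureShapes()].
#' @param metric column to summarise (`"fsi"` or `"sr"`).
#' @return data.frame with columns genotypeId, mu, sigma (sd is 0 for
#'   single-image genotypes).
#' @export
genotypeShapeStats <- function(shapes, metric = c("fsi", "sr")) {
  metric <- match.arg(metric)
  mu <- tapply(shapes[[metric]], shapes$genotypeId, mean)
  sg <- tapply(shapes[[metric]], shapes$genotypeId,
               function(v) if (length(v) > 1L) stats::sd(v) else 0)
  data.frame(genotypeId = names(mu), mu = as.numeric(mu),
             sigma = as.numeric(sg), stringsAsFactors = FALSE)
}

#' First-order Wasserstein distance between two univariate samples
#'
#' The area between the two empirical distribution functions, equal to the
#' integrated absolute difference of the quantile functions (for equal-sized
#' samples: the mean absolute difference of the sorted values).
#'
#' @param a,b nonempty numeric vectors.
#' @return the distance, a non-negative real.
#' @examples
#' wasserstein1d(c(0, 0), c(0.5, 0.5))  # 0.5
#' @export
wasserstein1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  all_v <- sort(c(a, b))
  if (length(all_v) == 1L) return(0)
  xs <- all_v[-length(all_v)]
  dx <- diff(all_v)
  fa <- stats::ecdf(a)(xs)
  fb <- stats::ecdf(b)(xs)
  sum(abs(fa - fb) * dx)
}

#' Shape-class confusion analysis
#'
#' Confusion matrix over the five shape categories (fixed order: flat,
#' flat-globose, globose, oval, oblong; true classes in rows), overall
#' accuracy, and the macro-averaged F score over the classes present in the
#' true labels.
#'
#' @param trueCat,predCat vectors of category labels (character or factor
#'   with levels among the five categories); equal length.
#' @return list with elements `confusion` (5 x 5 matrix), `accuracy` and
#'   `fScore`.
#' @export
shapeConfusion <- function(trueCat, predCat) {
  if (length(trueCat) != length(predCat))
    stop("label vectors must have equal length", call. = FALSE)
  to_factor <- function(x) {
    x <- as.character(x)
    bad <- setdiff(unique(x), SHAPE_CATEGORIES)
    if (length(bad))
      stop("unknown shape label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    factor(x, levels = SHAPE_CATEGORIES)
  }
  tc <- to_factor(trueCat)
  pc <- to_factor(predCat)
  conf <- table(true = tc, predicted = pc)
  conf <- matrix(conf, 5L, 5L, dimnames = list(true = SHAPE_CATEGORIES,
                                               predicted = SHAPE_CATEGORIES))
  acc <- sum(diag(conf)) / sum(conf)
  present <- which(rowSums(conf) > 0)
  f1 <- vapply(present, function(k) {
    tp <- conf[k, k]
    prec <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec <- tp / sum(conf[k, ])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(confusion = conf, accuracy = acc, fScore = mean(f1))
}

#' Compare two batteries of model MAEs
#'
#' Welch's two-sample t test (the group variances of independently trained
#' model batteries need not be equal) on the MAE values of two batteries of
#' trained models.
#'
#' @param maeA,maeB numeric vectors of per-model MAEs, each of length >= 2.
#' @param alternative passed to [stats::t.test()] (`"two.sided"` by default;
#'   use `"less"` for the directional hypothesis that battery A has lower
#'   MAE).
#' @return list with `t`, `p`, `means`, `sds`.
#' @export
compareModelBatteries <- function(maeA, maeB,
                                  alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  if (length(maeA) < 2L || length(maeB) < 2L)
    stop("each battery needs at least 2 MAE values", call. = FALSE)
  tt <- stats::t.test(maeA, maeB, alternative = alternative,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       means = c(A = mean(maeA), B = mean(maeB)),
       sds = c(A = stats::sd(maeA), B = stats::sd(maeB)))
}

# train one predictor on a panel and return its validation MAE
train_panel_model <- function(genotypes, panel, targets, valGenotypes,
                              hiddenUnits = 300L, maxEpochs = 1000L,
                              seed = 1L, ...) {
  spec <- predictorSpec(length(snpIds(panel)), hiddenUnits = hiddenUnits,
                        outputDim = ncol(
                          if (is(targets, "GenotypeEmbeddingTargets"))
                            targets@embeddings else targets),
                        maxEpochs = maxEpochs, ...)
  pred <- buildPredictor(spec, seed = seed)
  pred <- trainPredictor(pred, genotypes, panel, targets,
                         valGenotypes = valGenotypes, seed = seed)
  pred
}

#' Panel-size ladder experiment
#'
#' For each panel size and each panel kind -- `augmented` (the full targeted
#' core plus random fill) and `random` (fully random) -- trains
#' `modelsPerSize` embedding predictors, each with a freshly drawn panel and
#' fresh weights (random selections are renewed for every model), and
#' records the validation MAE. This probes how diluting a targeted panel
#' with unrelated markers degrades a simple predictor.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param targets a [GenotypeEmbeddingTargets-class] (train + validation
#'   genotypes).
#' @param valGenotypes validation genotype ids.
#' @param targetedIds the targeted SNP core (required for the augmented
#'   kind; every size must be >= its length).
#' @param sizes integer vector of total panel sizes.
#' @param modelsPerSize models trained per (size, kind) cell.
#' @param kinds panel kinds to run.
#' @param hiddenUnits,maxEpochs predictor settings.
#' @param seed integer master seed; per-model seeds are derived from it.
#' @return list with `results` (tidy data.frame: size, kind, replicate,
#'   valMAE, seed) and `summary` (median and IQR per size x kind cell).
#' @export
panelLadderExperiment <- function(genotypes, targets, valGenotypes,
                                  targetedIds, sizes,
                                  modelsPerSize = 15L,
                                  kinds = c("augmented", "random"),
                                  hiddenUnits = 300L, maxEpochs = 1000L,
                                  seed = 1L) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  sizes <- vapply(sizes, assert_count, integer(1), name = "sizes")
  if ("augmented" %in% kinds && any(sizes < length(targetedIds)))
    stop("every ladder size must be >= the targeted core for augmented panels",
         call. = FALSE)
  if (any(sizes > length(colnames(genotypes@values))))
    stop("ladder size exceeds the SNP count", call. = FALSE)
  rows <- list()
  k <- 0L
  for (size in sizes) {
    for (kind in kinds) {
      for (rep_i in seq_len(modelsPerSize)) {
        k <- k + 1L
        mseed <- (seed * 10007L + k * 97L) %% .Machine$integer.max
        panel <- if (kind == "augmented")
          selectPanel(genotypes, "augmented", nTotal = size,
                      targetedIds = targetedIds, seed = mseed)
        else
          selectPanel(genotypes, "random", nTotal = size, seed = mseed)
        mod <- train_panel_model(genotypes, panel, targets, valGenotypes,
                                 hiddenUnits = hiddenUnits,
                                 maxEpochs = maxEpochs, seed = mseed)
        rows[[k]] <- data.frame(size = size, kind = kind,
                                replicate = rep_i, valMAE = mod@valMAE,
                                seed = mseed)
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results,
                                      list(results$size, results$kind),
                                      drop = TRUE), function(d)
    data.frame(size = d$size[1L], kind = d$kind[1L],
               median = stats::median(d$valMAE), iqr = stats::IQR(d$valMAE),
               n = nrow(d))))
  rownames(summ) <- NULL
  list(results = results, summary = summ[order(summ$kind, summ$size), ])
}

#' Evaluate an assembled SNP-to-image model on validation genotypes
#'
#' Computes the full evaluation report: embedding MAE against the
#' mean-embedding targets; FSI and SR MAE of the drawn images against the
#' decoded per-genotype means; the resampling null threshold from the
#' original images' per-genotype FSI distributions; Wasserstein distances
#' between the predicted, decoded-mean and (when original images are given)
#' original FSI distributions; and the five-class shape confusion of
#' predicted vs decoded categories. The report echoes the thresholds, seed
#' and panel composition that produced it.
#'
#' @param model a [GenoDrawingModel-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @param targets a [GenotypeEmbeddingTargets-class] with decoded mean
#'   images for the validation genotypes (see [buildGenotypeTargets()]).
#' @param valGenotypes validation genotype ids.
#' @param images optional [FruitImageSet-class] of original validation
#'   images, used for the null threshold and the original-distribution
#'   Wasserstein distances.
#' @param thresholds FSI category cut points.
#' @param nullDatasets resampled datasets for the null threshold.
#' @param seed integer seed (null-threshold resampling).
#' @return an [EvalReport-class].
#' @export
evaluateGenoDrawing <- function(model, genotypes, targets, valGenotypes,
                                images = NULL,
                                thresholds = DEFAULT_FSI_THRESHOLDS,
                                nullDatasets = 10000L, seed = 1L) {
  stopifnot(is(model, "GenoDrawingModel"),
            is(targets, "GenotypeEmbeddingTargets"))
  val <- intersect(valGenotypes, rownames(targets@embeddings))
  if (!length(val)) stop("no validation genotypes in targets", call. = FALSE)

  pred_emb <- predictEmbeddings(model@predictor, genotypes)[val, ,
                                                            drop = FALSE]
  emb_mae <- embeddingMAE(pred_emb, targets@embeddings[val, , drop = FALSE])

  drawn <- lapply(val, function(g)
    drawGenotype(model, genotypes, genotypeId = g))
  pred_shape <- measureShapes(drawn, thresholds = thresholds)
  dec <- targets@decodedImages[val]
  if (any(vapply(dec, is.null, logical(1))))
    stop("targets lack decoded mean images for validation genotypes",
         call. = FALSE)
  dec_shape <- measureShapes(dec, thresholds = thresholds)

  fsi_mae <- mean(abs(pred_shape$fsi - dec_shape$fsi))
  sr_mae <- mean(abs(pred_shape$sr - dec_shape$sr))

  wd <- c(predicted_vs_decoded = wasserstein1d(pred_shape$fsi,
                                               dec_shape$fsi))
  null_b <- c(mean = NA_real_, sd = NA_real_)
  if (!is.null(images)) {
    vimg <- images[val]
    osh <- measureShapes(vimg, thresholds = thresholds)
    gstats <- genotypeShapeStats(osh, "fsi")
    null_b <- nullThreshold(gstats, nDatasets = nullDatasets, seed = seed)
    wd <- c(wd,
            predicted_vs_original = wasserstein1d(pred_shape$fsi, osh$fsi),
            decoded_vs_original = wasserstein1d(dec_shape$fsi, osh$fsi))
  }
  conf <- shapeConfusion(dec_shape$category, pred_shape$category)

  new("EvalReport", embeddingMAE = emb_mae, fsiMAE = fsi_mae, srMAE = sr_mae,
      nullBoundary = null_b, wasserstein = wd, confusion = conf$confusion,
      accuracy = conf$accuracy, fScore = conf$fScore,
      config = list(thresholds = thresholds, seed = seed,
                    nullDatasets = nullDatasets,
                    panel = list(kind = model@panel@kind,
                                 nTargeted = model@panel@nTargeted,
                                 nRandom = model@panel@nRandom,
                                 seed = model@panel@seed),
                    valGenotypes = val))
}
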