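test_that("the predictor has the stated two-layer shape and parameter count", {
  pred <- buildPredictor(predictorSpec(150, hiddenUnits = 300,
                                       outputDim = 64))
  # 150*300 + 300 + 300*64 + 64
  expect_equal(nParameters(pred), 64564L)
  x <- genoDraw:::with_seed(1,
    matrix(sample(c(0, 0.5, 1), 5 * 150, replace = TRUE), 5, 150))
  out <- predictEmbeddings(pred, x)
  expect_equal(dim(out), c(5, 64))
  expect_true(all(out > 0 & out < 1))
  # the panel-ladder maximum input width builds
  big <- buildPredictor(predictorSpec(300150))
  expect_equal(big@spec@nSnps, 300150L)
})

test_that("constant targets are learned to near-zero validation MAE", {
  fx <- fix_population()
  gm <- fx$pop$genotypes
  gids <- sampleIds(gm)
  tgt <- matrix(0.4, length(gids), 8,
                dimnames = list(gids, NULL))
  spec <- predictorSpec(10, hiddenUnits = 16, outputDim = 8,
                        maxEpochs = 300)
  pred <- buildPredictor(spec, seed = 1)
  pred <- trainPredictor(pred, gm, fx$pop$causalSnps, tgt,
                         valGenotypes = gids[1:7], seed = 1)
  expect_lt(pred@valMAE, 0.01)
})

test_that("targets unrelated to the SNPs converge to the mean-vector MAE", {
  fx <- fix_population()
  gm <- fx$pop$genotypes
  gids <- sampleIds(gm)
  tgt <- genoDraw:::with_seed(11, {
    base <- matrix(runif(length(gids) * 6, 0.3, 0.7), length(gids), 6)
    rownames(base) <- sample(gids)  # shuffled: no genotype-target link
    base
  })
  val <- rownames(tgt)[1:10]
  spec <- predictorSpec(10, hiddenUnits = 32, outputDim = 6,
                        maxEpochs = 400)
  pred <- buildPredictor(spec, seed = 2)
  pred <- trainPredictor(pred, gm, fx$pop$causalSnps, tgt,
                         valGenotypes = val, seed = 2)
  # analytic baseline: MAE of predicting the training mean vector
  tr_mean <- colMeans(tgt[setdiff(rownames(tgt), val), ])
  baseline <- mean(abs(sweep(tgt[val, ], 2, tr_mean)))
  expect_lt(abs(pred@valMAE - baseline), 0.35 * baseline)
})

test_that("missing genotypes and panel SNPs are errors naming the culprit", {
  fx <- fix_population()
  gm <- fx$pop$genotypes
  tgt <- matrix(0.5, 3, 4,
                dimnames = list(c(sampleIds(gm)[1:2], "GHOST"), NULL))
  spec <- predictorSpec(10, hiddenUnits = 4, outputDim = 4, maxEpochs = 2)
  pred <- buildPredictor(spec)
  expect_error(trainPredictor(pred, gm, fx$pop$causalSnps, tgt), "GHOST")
  tgt2 <- matrix(0.5, 2, 4, dimnames = list(sampleIds(gm)[1:2], NULL))
  expect_error(trainPredictor(pred, gm, c(fx$pop$causalSnps[1:9], "SNPX"),
                              tgt2), "SNPX")
})

test_that("the early stopper sits out a strictly improving fit", {
  # constant target, tiny model: validation MAE decreases essentially every
  # epoch, so training must run well past the early-stop patience
  fx <- fix_population()
  gm <- fx$pop$genotypes
  gids <- sampleIds(gm)
  tgt <- matrix(rep(seq(0.2, 0.8, length.out = 4), each = length(gids)),
                length(gids), 4, dimnames = list(gids, NULL))
  spec <- predictorSpec(10, hiddenUnits = 8, outputDim = 4, maxEpochs = 120,
                        earlyStopPatience = 10, learningRate = 0.02)
  pred <- buildPredictor(spec, seed = 3)
  pred <- trainPredictor(pred, gm, fx$pop$causalSnps, tgt,
                         valGenotypes = gids[1:7], seed = 3)
  expect_gt(nrow(lossHistory(pred)), 100)
})

test_that("assembly composes without touching weights", {
  fx <- fix_population()
  ae <- fix_autoencoder_full()
  tg <- fix_targets()
  panel <- selectPanel(fx$pop$genotypes, "targeted",
                       targetedIds = fx$pop$causalSnps)
  spec <- predictorSpec(10, hiddenUnits = 32, outputDim = 64,
                        maxEpochs = 60)
  pred <- buildPredictor(spec, seed = 4)
  pred <- trainPredictor(pred, fx$pop$genotypes, panel, tg,
                         valGenotypes = valGenotypes(fx$split), seed = 4)
  w_before <- pred@layers[[1]]$W
  model <- assembleGenoDrawing(pred, ae, panel)
  expect_identical(model@predictor@layers[[1]]$W, w_before)
  expect_identical(model@decoder, ae@decoder)

  g <- sampleIds(fx$pop$genotypes)[1]
  img <- drawGenotype(model, fx$pop$genotypes, genotypeId = g)
  # exact functional composition decode(predict(.))
  emb <- predictEmbeddings(pred, fx$pop$genotypes)[g, ]
  ref <- decodeEmbeddings(ae, emb)
  expect_equal(img, array(ref, dim(ref)[1:3]))
  # determinism
  expect_identical(img, drawGenotype(model, fx$pop$genotypes,
                                     genotypeId = g))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("assembly and drawing validate their inputs", {
  fx <- fix_population()
  ae <- fix_autoencoder_full()
  panel <- selectPanel(fx$pop$genotypes, "targeted",
                       targetedIds = fx$pop$causalSnps)
  bad <- buildPredictor(predictorSpec(10, outputDim = 32))
  expect_error(assembleGenoDrawing(bad, ae, panel), "expects 64")

  spec <- predictorSpec(10, hiddenUnits = 8, outputDim = 64, maxEpochs = 2)
  pred <- buildPredictor(spec, seed = 1)
  pred <- trainPredictor(pred, fx$pop$genotypes, panel, fix_targets(),
                         seed = 1)
  model <- assembleGenoDrawing(pred, ae, panel)
  row <- stats::setNames(rep(0.5, 9), snpIds(panel)[1:9])
  expect_error(drawGenotype(model, row), snpIds(panel)[10])
  row2 <- stats::setNames(rep(0.3, 10), snpIds(panel))
  expect_error(drawGenotype(model, row2), "0, 0.5, 1")
  # an untrained model still draws a valid image
  fresh <- assembleGenoDrawing(buildPredictor(predictorSpec(
    10, outputDim = 64), seed = 9), ae, panel)
  img <- drawGenotype(fresh, stats::setNames(rep(0.5, 10), snpIds(panel)))
  expect_true(all(img >= 0 & img <= 1))
})
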