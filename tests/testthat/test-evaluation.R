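test_that("embedding MAE equals the brute-force double loop", {
  a <- matrix(0.5, 3, 4)
  expect_equal(embeddingMAE(a, a), 0)
  expect_equal(embeddingMAE(a + 0.1, a), 0.1)
  p <- genoDraw:::with_seed(1, matrix(runif(5 * 64), 5, 64))
  t <- genoDraw:::with_seed(2, matrix(runif(5 * 64), 5, 64))
  brute <- 0
  for (i in 1:5) for (j in 1:64) brute <- brute + abs(p[i, j] - t[i, j])
  expect_equal(embeddingMAE(p, t), brute / (5 * 64))
  expect_error(embeddingMAE(p, t[1:4, ]), "identical shapes")
})

test_that("the resampling null threshold is calibrated", {
  g36 <- data.frame(genotypeId = sprintf("G%02d", 1:36),
                    mu = seq(0.8, 1.2, length.out = 36), sigma = 0)
  nb <- nullThreshold(g36, nDatasets = 100, seed = 1)
  expect_equal(unname(nb["mean"]), 0)
  expect_equal(unname(nb["sd"]), 0)

  # equal sigmas: the replicate MAE converges to the half-normal mean
  s <- 0.07
  g36$sigma <- s
  nb <- nullThreshold(g36, nDatasets = 10000, seed = 1)
  expect_equal(unname(nb["mean"]), s * sqrt(2 / pi),
               tolerance = 0.02)
  expect_gt(unname(nb["sd"]), 0)

  # seeded determinism
  expect_identical(nullThreshold(g36, nDatasets = 500, seed = 9),
                   nullThreshold(g36, nDatasets = 500, seed = 9))
  expect_error(nullThreshold(data.frame(mu = 1, sigma = -1)), "non-negative")
})

test_that("1-D Wasserstein distance matches oracles and is a metric", {
  expect_equal(wasserstein1d(c(0, 0, 0), c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(wasserstein1d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  for (rep in 1:5) {
    a <- runif(50); b <- runif(50)
    # equal sizes: mean absolute difference of sorted samples
    expect_equal(wasserstein1d(a, b), mean(abs(sort(a) - sort(b))))
    expect_equal(wasserstein1d(a, b), wasserstein1d(b, a))
    cc <- runif(30)
    expect_lte(wasserstein1d(a, cc),
               wasserstein1d(a, b) + wasserstein1d(b, cc) + 1e-12)
  }
  expect_error(wasserstein1d(numeric(0), 1), "empty")
})

test_that("shape confusion matches a hand-computed oracle", {
  truth <- c("flat", "flat", "globose", "globose", "oval", "oval", "oval",
             "flat-globose", "flat-globose", "flat")
  pred <- c("flat", "globose", "globose", "globose", "oval", "flat", "oval",
            "flat-globose", "flat", "flat")
  res <- shapeConfusion(truth, pred)
  expect_equal(sum(res$confusion), 10)
  expect_equal(unname(rowSums(res$confusion)),
               c(3, 2, 2, 3, 0))  # per-class true counts
  expect_equal(res$accuracy, 7 / 10)
  # per class (present in truth): precision/recall computed by hand
  # flat: tp=2, fp=2, fn=1 -> P=0.5, R=2/3, F=4/7
  # flat-globose: tp=1, fp=0, fn=1 -> F=2/3
  # globose: tp=2, fp=1, fn=0 -> P=2/3, R=1, F=0.8
  # oval: tp=2, fp=0, fn=1 -> P=1, R=2/3, F=0.8
  expect_equal(res$fScore, mean(c(4 / 7, 2 / 3, 0.8, 0.8)))

  perfect <- shapeConfusion(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fScore, 1)

  collapse <- shapeConfusion(rep(c("flat", "oval"), each = 5),
                             rep("flat", 10))
  expect_equal(collapse$accuracy, 0.5)
  expect_error(shapeConfusion("flat", "pear"), "pear")
})

test_that("battery comparison is a Welch t test with group summaries", {
  same <- c(0.08, 0.09, 0.10)
  res <- compareModelBatteries(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$means, c(A = 0.09, B = 0.09))
  expect_error(compareModelBatteries(0.1, same), "at least 2")

  # Monte-Carlo power check: N(0.08, 0.003) vs N(0.09, 0.002), n = 30
  hits <- 0
  set.seed(7)
  for (r in 1:100) {
    a <- rnorm(30, 0.08, 0.003)
    b <- rnorm(30, 0.09, 0.002)
    if (compareModelBatteries(a, b)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the panel ladder bookkeeps sizes, kinds and replicates", {
  fx <- fix_population()
  tg <- fix_targets()
  res <- panelLadderExperiment(fx$pop$genotypes, tg,
                               valGenotypes(fx$split),
                               targetedIds = fx$pop$causalSnps,
                               sizes = c(10, 20), modelsPerSize = 3,
                               hiddenUnits = 8, maxEpochs = 3, seed = 1)
  expect_equal(nrow(res$results), 12)  # 2 sizes x 2 kinds x 3 replicates
  expect_setequal(unique(res$results$kind), c("augmented", "random"))
  expect_equal(nrow(res$summary), 4)
  expect_true(all(res$results$valMAE >= 0))
  expect_error(panelLadderExperiment(fx$pop$genotypes, tg,
                                     valGenotypes(fx$split),
                                     targetedIds = fx$pop$causalSnps,
                                     sizes = 5, modelsPerSize = 1),
               "targeted core")
})

test_that("the evaluation report is complete and echoes its provenance", {
  fx <- fix_population()
  ae <- fix_autoencoder_full()
  tg <- fix_targets()
  panel <- selectPanel(fx$pop$genotypes, "targeted",
                       targetedIds = fx$pop$causalSnps)
  pred <- buildPredictor(predictorSpec(10, hiddenUnits = 64,
                                       outputDim = 64, maxEpochs = 150),
                         seed = 6)
  pred <- trainPredictor(pred, fx$pop$genotypes, panel, tg,
                         valGenotypes = valGenotypes(fx$split), seed = 6)
  model <- assembleGenoDrawing(pred, ae, panel)
  rep <- evaluateGenoDrawing(model, fx$pop$genotypes, tg,
                             valGenotypes(fx$split),
                             images = fx$pop$images, nullDatasets = 2000,
                             seed = 3)
  expect_gte(rep@embeddingMAE, 0)
  expect_gte(rep@fsiMAE, 0)
  expect_gte(rep@srMAE, 0)
  expect_equal(sum(rep@confusion), length(valGenotypes(fx$split)))
  expect_equal(rep@accuracy, sum(diag(rep@confusion)) / sum(rep@confusion))
  expect_named(rep@wasserstein, c("predicted_vs_decoded",
                                  "predicted_vs_original",
                                  "decoded_vs_original"))
  # full provenance echo
  expect_equal(rep@config$thresholds, c(0.85, 0.95, 1.05, 1.20))
  expect_equal(rep@config$seed, 3)
  expect_equal(rep@config$panel$kind, "targeted")
  expect_setequal(rep@config$valGenotypes, valGenotypes(fx$split))
})
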