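test_that("the full-scale architecture matches its contract at 300 px", {
  ae <- buildAutoencoder(autoencoderSpec(), imageSize = 300, seed = 1)
  dense <- Filter(function(l) l$type == "dense", ae@encoder)
  expect_equal(vapply(dense, function(l) l$n_out, numeric(1)),
               c(8192, 4096, 2048, 64))
  convs <- Filter(function(l) l$type == "conv", ae@encoder)
  expect_length(convs, 6)
  expect_equal(vapply(convs, function(l) l$out_shape[3], numeric(1)),
               c(16, 32, 48, 64, 96, 128))
  # decoder mirrors the encoder layer-for-layer
  ddense <- Filter(function(l) l$type == "dense", ae@decoder)
  expect_equal(vapply(ddense, function(l) l$n_out, numeric(1)),
               c(2048, 4096, 8192, 128 * 5 * 5))
  dconv <- Filter(function(l) l$type == "convt", ae@decoder)
  expect_equal(vapply(dconv, function(l) l$out_shape[1], numeric(1)),
               c(10, 19, 38, 75, 150, 300))  # inverts 300>150>75>38>19>10>5
  # single forward pass: bottleneck and output ranges
  x <- genoDraw:::with_seed(2, array(runif(300 * 300 * 3), c(300, 300, 3, 1)))
  emb <- encodeImages(ae, x)
  expect_equal(ncol(emb), 64)
  expect_true(all(emb >= 0 & emb <= 1))
  rec <- decodeEmbeddings(ae, emb)
  expect_equal(dim(rec)[1:3], c(300, 300, 3))
  expect_true(all(rec >= 0 & rec <= 1))
  rm(ae, rec); gc(verbose = FALSE)
})

test_that("incompatible image sizes fail with the offending dimension", {
  expect_error(buildAutoencoder(autoencoderSpec(), imageSize = 16),
               "convolution 4.*below 2 px")
})

test_that("training on one repeated image reduces the loss", {
  img <- renderFruit(shapeParams(fsi = 1.1), imageSize = 64)
  imgs <- fruitImageSet(rep(list(array(as.numeric(img), dim(img))), 8),
                        genotypeId = rep("G1", 8))
  ae <- buildAutoencoder(deskAutoencoderSpec(), imageSize = 64, seed = 3)
  ae <- trainAutoencoder(ae, imgs, loss = "mse", epochs = 5, seed = 3)
  h <- lossHistory(ae)
  expect_length(h, 5)
  expect_lt(h[length(h)], h[1])
})

test_that("perceptual loss is an explicit error advising the alternatives", {
  ae <- buildAutoencoder(deskAutoencoderSpec(), imageSize = 64, seed = 3)
  imgs <- fruitImageSet(list(array(0.5, c(64, 64, 3))), "G1")
  expect_error(trainAutoencoder(ae, imgs, loss = "perceptual"),
               "pretrained feature-extractor")
})

test_that("ssim loss trains as an alternative reconstruction objective", {
  img <- renderFruit(shapeParams(fsi = 0.9), imageSize = 64)
  imgs <- fruitImageSet(rep(list(array(as.numeric(img), dim(img))), 6),
                        genotypeId = rep("G1", 6))
  ae <- buildAutoencoder(deskAutoencoderSpec(), imageSize = 64, seed = 4)
  ae <- trainAutoencoder(ae, imgs, loss = "ssim", epochs = 4,
                         learningRate = 0.05, seed = 4)
  h <- lossHistory(ae)
  expect_lt(h[length(h)], h[1])
})

test_that("encoding is deterministic and bounded to [0,1]", {
  ae <- fix_autoencoder()
  fx <- fix_population()
  some <- fx$pop$images[genotypeIds(fx$pop$images) %in%
                          trainGenotypes(fx$split)[1:2]]
  e1 <- encodeImages(ae, some)
  e2 <- encodeImages(ae, some)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0 & e1 <= 1))
  expect_equal(ncol(e1), 64)
  # identical images yield identical embeddings
  twice <- fruitImageSet(list(getImage(some, 1), getImage(some, 1)),
                         c("A", "B"))
  et <- encodeImages(ae, twice)
  expect_equal(et[1, ], et[2, ], ignore_attr = TRUE)
  # size mismatch is an explicit error
  expect_error(encodeImages(ae, array(0.5, c(32, 32, 3, 1))), "expects 64x64")
})

test_that("a trained encoder separates shapes beyond replicate noise", {
  ae <- fix_autoencoder_full()
  narrow <- renderFruit(shapeParams(fsi = 0.75), imageSize = 64)
  wide <- renderFruit(shapeParams(fsi = 1.35), imageSize = 64)
  rep1 <- renderFruit(shapeParams(fsi = 1.00), imageSize = 64)
  rep2 <- renderFruit(shapeParams(fsi = 1.02), imageSize = 64)
  strip <- function(x) array(as.numeric(x), dim(x))
  e <- encodeImages(ae, list(strip(narrow), strip(wide), strip(rep1),
                             strip(rep2)))
  d_shapes <- sqrt(sum((e[1, ] - e[2, ])^2))
  d_reps <- sqrt(sum((e[3, ] - e[4, ])^2))
  expect_gt(d_shapes, d_reps)
})

test_that("mean-embedding targets equal an independent brute-force mean", {
  ae <- fix_autoencoder()
  fx <- fix_population()
  emb <- encodeImages(ae, fx$pop$images)
  gids <- genotypeIds(fx$pop$images)
  tg <- buildGenotypeTargets(emb, gids, ae = ae)
  # brute force: explicit double loop over genotypes and dimensions
  for (g in unique(gids)[1:5]) {
    rows <- which(gids == g)
    manual <- vapply(seq_len(ncol(emb)), function(j) {
      s <- 0
      for (r in rows) s <- s + emb[r, j]
      s / length(rows)
    }, numeric(1))
    expect_equal(unname(embeddings(tg)[g, ]), manual)
  }
  expect_equal(nrow(embeddings(tg)), 70)
  expect_equal(ncol(embeddings(tg)), 64)
  expect_length(decodedImages(tg), 70)
})

test_that("decoding the mean of identical embeddings equals decoding one", {
  ae <- fix_autoencoder()
  fx <- fix_population()
  img <- getImage(fx$pop$images, 1)
  e <- encodeImages(ae, list(img, img))
  tg <- buildGenotypeTargets(e, c("G", "G"), ae = ae)
  expect_equal(unname(embeddings(tg)["G", ]), unname(e[1, ]))
  single <- decodeEmbeddings(ae, e[1, ])
  expect_equal(decodedImages(tg)[["G"]], array(single, dim(single)[1:3]))
})

test_that("a genotype with zero images is an error", {
  f <- factor(c("A", "A"), levels = c("A", "B"))
  expect_error(buildGenotypeTargets(matrix(0.5, 2, 4), f), "zero images")
})

test_that("model checkpoints round trip through a single file", {
  ae <- fix_autoencoder()
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(ae, path)
  back <- loadModel(path)
  expect_identical(back@encoder, ae@encoder)
  expect_identical(back@spec@denseSizes, ae@spec@denseSizes)
  saveRDS(1:3, path)
  expect_error(loadModel(path), "checkpoint")
})
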