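# Shared desk-scale fixtures, built once per test run and memoised. The
# population emulates the study design: a few hundred images over dozens of
# genotypes, a small causal SNP set additively controlling the fruit shape
# index plus many neutral SNPs, and several images per genotype with
# within-genotype environmental variability.

.fixtures <- new.env(parent = emptyenv())

fix_arch <- function() {
  geneticArchitecture(nCausal = 10, nNeutral = 140,
                      effectSizes = rep(c(0.04, -0.04), 5),
                      baselineFsi = 0.95, envSd = 0.03, alleleFreqs = 0.5)
}

fix_population <- function() {
  if (is.null(.fixtures$pop)) {
    .fixtures$pop <- simulatePopulation(fix_arch(), nGenotypes = 70,
                                        imagesPerGenotype = 5,
                                        imageSize = 64, seed = 2024)
    .fixtures$split <- suppressWarnings(
      stratifiedSplit(.fixtures$pop$images, trainFraction = 0.9, seed = 7))
  }
  list(pop = .fixtures$pop, split = .fixtures$split)
}

# the 15-epoch desk-profile training run
fix_autoencoder <- function() {
  if (is.null(.fixtures$ae)) {
    fx <- fix_population()
    tr <- fx$pop$images[trainGenotypes(fx$split)]
    ae <- buildAutoencoder(deskAutoencoderSpec(), imageSize = 64, seed = 5)
    .fixtures$ae <- trainAutoencoder(ae, tr, loss = "mse", epochs = 15,
                                     seed = 5)
  }
  .fixtures$ae
}

# the same model trained on to 25 epochs: the fixture used for embeddings,
# targets and the predictor experiments
fix_autoencoder_full <- function() {
  if (is.null(.fixtures$ae_full)) {
    fx <- fix_population()
    tr <- fx$pop$images[trainGenotypes(fx$split)]
    .fixtures$ae_full <- trainAutoencoder(fix_autoencoder(), tr,
                                          loss = "mse", epochs = 10,
                                          seed = 6)
  }
  .fixtures$ae_full
}

fix_targets <- function() {
  if (is.null(.fixtures$targets)) {
    fx <- fix_population()
    ae <- fix_autoencoder_full()
    emb <- encodeImages(ae, fx$pop$images)
    .fixtures$targets <- buildGenotypeTargets(emb,
                                              genotypeIds(fx$pop$images),
                                              ae = ae)
  }
  .fixtures$targets
}

# a neutral-only panel of the same size as the causal set
fix_neutral_panel <- function(pop, n, seed) {
  neutral <- setdiff(snpIds(pop$genotypes), pop$causalSnps)
  ids <- genoDraw:::with_seed(seed, sample(neutral, n))
  new("SNPPanel", snpIds = ids, kind = "random", nTargeted = 0L,
      nRandom = as.integer(n), seed = as.integer(seed))
}

# measured FSI of decoded image i of an [H, W, 3, N] array
decoded_fsi <- function(arr, i) {
  fruitShapeIndex(extractSilhouette(arr[, , , i],
                                    provenance = "decoded_mean"))
}
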