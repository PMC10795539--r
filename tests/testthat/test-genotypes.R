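calls_fixture <- function() {
  matrix(c("AA", "Aa", "aa", "aA", "AA", "aa"), nrow = 3,
         dimnames = list(c("s1", "s2", "s3"), c("snpA", "snpB")))
}

test_that("allele calls encode to the 0/0.5/1 dosage scale", {
  gm <- encodeAlleles(calls_fixture())
  expect_equal(unname(dosages(gm)[, "snpA"]), c(0, 0.5, 1))
  expect_equal(unname(dosages(gm)[, "snpB"]), c(0.5, 0, 1))
  expect_equal(dim(dosages(gm)), c(3, 2))
  # heterozygote symmetry and full-grid values
  single <- function(call) {
    m <- matrix(call, 1, 1, dimnames = list("s", "x"))
    as.numeric(dosages(encodeAlleles(m)))
  }
  expect_identical(single("Aa"), single("aA"))
  expect_equal(c(single("AA"), single("Aa"), single("aa")), c(0, 0.5, 1))
})

test_that("unknown and missing calls fail fast, naming the cell", {
  calls <- calls_fixture()
  calls[2, 2] <- "AT"
  expect_error(encodeAlleles(calls), "AT.*s2.*snpB")
  calls[2, 2] <- NA
  expect_error(encodeAlleles(calls), "missing.*s2.*snpB")
  calls <- calls_fixture()
  calls[1, 2] <- NA   # observed snpB calls are AA (0) and aa (1)
  gm <- encodeAlleles(calls, impute = TRUE)
  expect_equal(unname(dosages(gm)[1, "snpB"]), 0.5)  # mean(0, 1) = 0.5
})

test_that("decode is the inverse of encode on canonical dosages", {
  gm <- encodeAlleles(calls_fixture())
  expect_identical(dosages(encodeAlleles(decodeAlleles(gm))), dosages(gm))
})

test_that("the GenotypeMatrix invariants are enforced", {
  v <- matrix(c(0, 0.5, 1, 0.3), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(genotypeMatrix(v), "0, 0.5, 1")
  v2 <- matrix(0, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(genotypeMatrix(v2), "duplicate sample")
  v3 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(genotypeMatrix(v3), "duplicate SNP")
})

test_that("CSV genotype files round trip and reject duplicate columns", {
  gm <- encodeAlleles(calls_fixture())
  path <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(gm, path)
  back <- loadGenotypes(path)
  expect_equal(dosages(back), dosages(gm))
  expect_identical(sampleIds(back), c("s1", "s2", "s3"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotypeId,snpA,snpA", "s1,0,1"), dup)
  expect_error(loadGenotypes(dup), "duplicated SNP")
  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("justonecolumn", hdr)
  expect_error(loadGenotypes(hdr), "malformed CSV header")
})

vcf_lines <- function(alt2 = "G") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    sprintf("1\t200\trs2\tC\t%s\t.\tPASS\t.\tGT\t0|1\t1/1\t0/0", alt2))
}

test_that("biallelic VCF loads with the dosage encoding", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(), path)
  gm <- loadGenotypes(path, format = "vcf")
  expect_equal(dim(dosages(gm)), c(3, 2))
  expect_equal(unname(dosages(gm)[, "rs1"]), c(0, 0.5, 1))
  expect_equal(unname(dosages(gm)["s1", "rs2"]), 0.5)  # phased het
})

test_that("multiallelic VCF sites are an error listing the site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(alt2 = "G,T"), path)
  expect_error(loadGenotypes(path, format = "vcf"), "multiallelic.*rs2")
})

test_that("panel selection honours kind, size and determinism", {
  pop <- fix_population()$pop
  gm <- pop$genotypes
  tids <- pop$causalSnps

  tp <- selectPanel(gm, "targeted", targetedIds = tids)
  expect_identical(snpIds(tp), tids)
  expect_equal(tp@nRandom, 0L)

  ap <- selectPanel(gm, "augmented", nTotal = 100, targetedIds = tids,
                    seed = 3)
  expect_length(snpIds(ap), 100)
  expect_true(all(tids %in% snpIds(ap)))
  expect_identical(snpIds(selectPanel(gm, "augmented", nTotal = 100,
                                      targetedIds = tids, seed = 3)),
                   snpIds(ap))

  r1 <- selectPanel(gm, "random", nTotal = 50, seed = 1)
  r2 <- selectPanel(gm, "random", nTotal = 50, seed = 2)
  expect_false(identical(sort(snpIds(r1)), sort(snpIds(r2))))
  expect_identical(snpIds(selectPanel(gm, "random", nTotal = 50, seed = 1)),
                   snpIds(r1))

  expect_error(selectPanel(gm, "targeted", targetedIds = c(tids, "NOPE")),
               "NOPE")
  expect_error(selectPanel(gm, "augmented", nTotal = 5, targetedIds = tids),
               "smaller than the targeted core")
})

test_that("panel files round trip", {
  pop <- fix_population()$pop
  panel <- selectPanel(pop$genotypes, "targeted",
                       targetedIds = pop$causalSnps)
  path <- withr::local_tempfile(fileext = ".txt")
  writePanel(panel, path)
  expect_identical(readSnpList(path), snpIds(panel))
})
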