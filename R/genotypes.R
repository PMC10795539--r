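# SNP genotype handling: allele encoding, CSV/VCF readers, panel selection.

#' Construct a GenotypeMatrix from a numeric dosage matrix
#'
#' @param values samples x SNPs numeric matrix with entries in \{0, 0.5, 1\},
#'   row names = sample ids, column names = SNP ids.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(values) {
  new("GenotypeMatrix", values = as.matrix(values))
}

#' Encode allele calls to numeric dosages
#'
#' Maps `AA -> 0`, `Aa`/`aA -> 0.5` (heterozygote order is ignored) and
#' `aa -> 1`. Unknown tokens are an error naming the offending row and
#' column. Missing calls (`NA`, or the declared `missingToken`) are an error
#' unless `impute = TRUE`, in which case each missing value is replaced by
#' its SNP's mean dosage rounded to the nearest valid dosage (0, 0.5 or 1),
#' so the matrix invariant is preserved and the imputation stays explicit.
#'
#' @param calls a character matrix of allele calls (samples x SNPs), with
#'   sample row names and SNP column names.
#' @param missingToken string treated as missing in addition to `NA`.
#' @param impute impute missing calls with the per-SNP rounded mean dosage?
#' @return a [GenotypeMatrix-class].
#' @examples
#' calls <- matrix(c("AA", "Aa", "aa", "aA"), 2, 2,
#'                 dimnames = list(c("s1", "s2"), c("snp1", "snp2")))
#' dosages(encodeAlleles(calls))
#' @export
encodeAlleles <- function(calls, missingToken = NULL, impute = FALSE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must carry sample row names and SNP column names",
         call. = FALSE)
  code <- c(AA = 0, Aa = 0.5, aA = 0.5, aa = 1)
  miss <- is.na(calls)
  if (!is.null(missingToken)) miss <- miss | calls == missingToken
  known <- miss | calls %in% names(code)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown allele call '%s' at sample '%s', SNP '%s'",
                 calls[bad[1L], bad[2L]], rownames(calls)[bad[1L]],
                 colnames(calls)[bad[2L]]), call. = FALSE)
  }
  vals <- matrix(code[calls], nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  if (any(miss)) {
    if (!impute) {
      bad <- which(miss, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing call at sample '%s', SNP '%s'; set impute = TRUE for per-SNP mean imputation",
        rownames(calls)[bad[1L]], colnames(calls)[bad[2L]]), call. = FALSE)
    }
    for (j in which(colSums(miss) > 0)) {
      m <- mean(vals[!miss[, j], j])
      if (is.nan(m)) stop(sprintf("SNP '%s' has no observed calls",
                                  colnames(calls)[j]), call. = FALSE)
      vals[miss[, j], j] <- round(m * 2) / 2
    }
  }
  genotypeMatrix(vals)
}

#' Decode numeric dosages back to allele calls
#'
#' The inverse of [encodeAlleles()] on its canonical output:
#' `0 -> AA`, `0.5 -> Aa`, `1 -> aa`.
#'
#' @param x a [GenotypeMatrix-class].
#' @return a character matrix of allele calls.
#' @export
decodeAlleles <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  v <- x@values
  out <- matrix(c("AA", "Aa", "aa")[match(v, c(0, 0.5, 1))],
                nrow(v), ncol(v), dimnames = dimnames(v))
  out
}

#' Load a genotype matrix from CSV or VCF
#'
#' CSV dialect: UTF-8, comma-separated, header row of SNP ids, first column
#' the genotype (sample) id, remaining cells numeric dosages in
#' \{0, 0.5, 1\} or allele calls (`AA`/`Aa`/`aA`/`aa`). VCF: biallelic sites
#' only (a multiallelic site is an error listing the site); the GT field is
#' encoded `0/0 -> 0`, `0/1 -> 0.5`, `1/1 -> 1` (phased separators accepted);
#' SNP ids come from the ID column, falling back to `CHROM_POS`.
#'
#' @param path file path.
#' @param format `"csv"` or `"vcf"`; guessed from the extension by default.
#' @param impute passed to [encodeAlleles()] for character CSV content, and
#'   controlling per-SNP rounded-mean imputation of missing VCF genotypes.
#' @return a [GenotypeMatrix-class].
#' @export
loadGenotypes <- function(path, format = c("auto", "csv", "vcf"),
                          impute = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  if (format == "csv") load_genotypes_csv(path, impute)
  else load_genotypes_vcf(path, impute)
}

load_genotypes_csv <- function(path, impute) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed CSV header: expected a genotype-id column plus SNP columns",
         call. = FALSE)
  snp_ids <- header[-1L]
  if (anyDuplicated(snp_ids))
    stop("duplicated SNP column(s) in CSV header: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
         call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  if (all(grepl("^\\s*[0-9.]+\\s*$", vals))) {
    storage.mode(vals) <- "numeric"
    genotypeMatrix(vals)
  } else {
    encodeAlleles(vals, impute = impute)
  }
}

load_genotypes_vcf <- function(path, impute) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  multi <- grepl(",", fix[, "ALT"])
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fix[, "ID"])
  if (any(multi))
    stop("multiallelic site(s) not supported: ",
         paste(ids[multi], collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- ids
  conv <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 0.5
    out[g %in% "1/1"] <- 1
    bad <- !is.na(g) & is.na(out)
    if (any(bad)) stop("unsupported GT value(s): ",
                       paste(unique(g[bad]), collapse = ", "), call. = FALSE)
    out
  }
  vals <- t(apply(gt, 1L, conv))   # sites x samples
  colnames(vals) <- colnames(gt)
  vals <- t(vals)                  # samples x sites
  if (anyNA(vals)) {
    if (!impute) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing genotype at sample '%s', site '%s'; set impute = TRUE",
        rownames(vals)[bad[1L]], colnames(vals)[bad[2L]]), call. = FALSE)
    }
    for (j in which(colSums(is.na(vals)) > 0)) {
      m <- mean(vals[, j], na.rm = TRUE)
      vals[is.na(vals[, j]), j] <- round(m * 2) / 2
    }
  }
  genotypeMatrix(vals)
}

#' Write a GenotypeMatrix as CSV
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output path; the dialect matches [loadGenotypes()].
#' @return invisibly, `path`.
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  df <- data.frame(genotypeId = rownames(x@values), x@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select an SNP panel from a genotype matrix
#'
#' Panel kinds mirror the targeted/random/diluted marker designs:
#' `targeted` returns exactly `targetedIds`; `random` draws `nTotal` SNPs
#' uniformly without replacement; `augmented` returns all of `targetedIds`
#' plus `nTotal - length(targetedIds)` random non-targeted SNPs. Random draws
#' are deterministic given `seed` and differ across seeds.
#'
#' @param x a [GenotypeMatrix-class].
#' @param kind `"targeted"`, `"random"` or `"augmented"`.
#' @param nTotal total panel size (ignored for `targeted`).
#' @param targetedIds character vector of targeted SNP ids (required for
#'   `targeted` and `augmented`); all must exist in `x`.
#' @param seed integer seed for the random draw.
#' @return an [SNPPanel-class].
#' @examples
#' pop <- simulatePopulation(geneticArchitecture(2, 8, rep(0.05, 2)),
#'                           nGenotypes = 4, imagesPerGenotype = 1,
#'                           imageSize = 64, seed = 1)
#' selectPanel(pop$genotypes, "augmented", nTotal = 5,
#'             targetedIds = pop$causalSnps, seed = 1)
#' @export
selectPanel <- function(x, kind = c("targeted", "random", "augmented"),
                        nTotal = NULL, targetedIds = NULL, seed = 1L) {
  stopifnot(is(x, "GenotypeMatrix"))
  kind <- match.arg(kind)
  all_ids <- colnames(x@values)
  if (kind %in% c("targeted", "augmented")) {
    if (is.null(targetedIds) || !length(targetedIds))
      stop("targetedIds required for ", kind, " panels", call. = FALSE)
    absent <- setdiff(targetedIds, all_ids)
    if (length(absent))
      stop("targeted SNP(s) absent from the genotype matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  if (kind == "targeted") {
    return(new("SNPPanel", snpIds = as.character(targetedIds),
               kind = "targeted", nTargeted = length(targetedIds),
               nRandom = 0L, seed = NA_integer_))
  }
  nTotal <- assert_count(nTotal, "nTotal", min = 1L)
  if (nTotal > length(all_ids))
    stop("nTotal exceeds the number of SNPs in the matrix", call. = FALSE)
  if (kind == "random") {
    ids <- with_seed(seed, sample(all_ids, nTotal))
    return(new("SNPPanel", snpIds = ids, kind = "random", nTargeted = 0L,
               nRandom = nTotal, seed = as.integer(seed)))
  }
  n_fill <- nTotal - length(targetedIds)
  if (n_fill < 0L)
    stop("nTotal is smaller than the targeted core for an augmented panel",
         call. = FALSE)
  pool <- setdiff(all_ids, targetedIds)
  if (n_fill > length(pool))
    stop("not enough non-targeted SNPs to fill the augmented panel",
         call. = FALSE)
  fill <- with_seed(seed, sample(pool, n_fill))
  new("SNPPanel", snpIds = c(as.character(targetedIds), fill),
      kind = "augmented", nTargeted = length(targetedIds),
      nRandom = n_fill, seed = as.integer(seed))
}

#' Write an SNP panel to a plain-text file
#'
#' One SNP id per line, panel order preserved.
#'
#' @param panel an [SNPPanel-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "SNPPanel"))
  writeLines(panel@snpIds, path)
  invisible(path)
}

#' Read a targeted-SNP list from a plain-text file
#'
#' @param path file with one SNP id per line (blank lines ignored).
#' @return character vector of SNP ids.
#' @export
readSnpList <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}
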