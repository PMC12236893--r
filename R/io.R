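#' Construct a GenotypeData object
#'
#' @param dosages numeric samples x variants matrix, values in [0,2] or NA;
#'   rownames are sample ids.
#' @param variants data.frame with variant_id, chrom, pos, ref, alt and
#'   optionally maf (computed empirically if absent), info_score (default 1)
#'   and block.
#' @return a [GenotypeData].
#' @export
GenotypeData <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%05d", seq_len(nrow(dosages)))
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(variants))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (is.null(variants$maf)) {
    f <- colMeans(dosages, na.rm = TRUE) / 2
    variants$maf <- pmin(f, 1 - f)
  }
  if (is.null(variants$info_score)) variants$info_score <- 1
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  names(rr) <- variants$variant_id
  mcols <- variants[, intersect(c("variant_id", "ref", "alt", "maf",
                                  "info_score", "block"),
                                colnames(variants)), drop = FALSE]
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(mcols)
  a <- t(dosages)
  rownames(a) <- variants$variant_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = a), rowRanges = rr)
  new("GenotypeData", se)
}

.gtToDosage <- function(gt) {
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
           "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA_real_,
           ".|." = NA_real_, "." = NA_real_)
  out <- map[gt]
  if (any(is.na(out) & !gt %in% names(map)))
    stop("unparseable GT value(s): ",
         paste(utils::head(unique(gt[!gt %in% names(map)]), 3), collapse = ", "))
  out
}

#' Read genotype dosages
#'
#' Reads either a VCF (\code{.vcf}, DS dosage field preferred, GT converted
#' to 0/1/2 otherwise) or a plain dosage-matrix TSV accompanied by a variant
#' table TSV. Sample and variant order are preserved; empirical minor allele
#' frequencies are computed and stored in the variant metadata; imputation
#' info scores are taken from the VCF \code{IS} INFO key (default 1).
#'
#' Multi-allelic VCF records are refused with an instruction to split them
#' (e.g. \code{bcftools norm -m-}).
#'
#' @param path VCF path, or dosage TSV path (sample_id column + one column
#'   per variant) when \code{variantTable} is given.
#' @param variantTable optional variant-table TSV (variant_id, chrom, pos,
#'   ref, alt, optionally info_score).
#' @return a [GenotypeData].
#' @export
readGenotypes <- function(path, variantTable = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(variantTable) && grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    if (any(nalt != 1L))
      stop("multi-allelic record(s) at ",
           paste(utils::head(rownames(vcf)[nalt != 1L], 3), collapse = ", "),
           "; split them first (e.g. 'bcftools norm -m-')")
    gen <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gen)) {
      d <- gen$DS
      storage.mode(d) <- "double"
    } else if ("GT" %in% names(gen)) {
      gt <- gen$GT
      d <- matrix(.gtToDosage(as.vector(gt)), nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    } else stop("VCF has neither DS nor GT genotype fields")
    if (any(d[!is.na(d)] < 0 | d[!is.na(d)] > 2))
      stop("dosages outside [0, 2] in ", path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    variants <- data.frame(
      variant_id = rownames(vcf),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = as.character(unlist(VariantAnnotation::alt(vcf))),
      info_score = if ("IS" %in% colnames(info)) as.numeric(info$IS) else 1,
      stringsAsFactors = FALSE)
    return(GenotypeData(t(d), variants))
  }
  if (is.null(variantTable))
    stop("matrix input requires a variantTable TSV")
  dosTab <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (colnames(dosTab)[1] != "sample_id")
    stop("dosage matrix TSV must start with a sample_id column")
  v <- utils::read.delim(variantTable, stringsAsFactors = FALSE)
  d <- as.matrix(dosTab[, -1, drop = FALSE])
  rownames(d) <- dosTab$sample_id
  if (!identical(colnames(d), v$variant_id))
    stop("dosage columns do not match the variant table")
  if (any(d[!is.na(d)] < 0 | d[!is.na(d)] > 2))
    stop("dosages outside [0, 2] in ", path)
  v$chrom <- as.character(v$chrom)
  GenotypeData(d, v)
}

#' Write genotypes as VCFv4.2 with GT and DS fields
#'
#' Emits one bi-allelic record per variant; GT is the rounded dosage,
#' DS the dosage itself, and the \code{IS} INFO key carries the imputation
#' info score. Reading the file back with [readGenotypes()] reproduces the
#' object (DS is preferred on input).
#'
#' @param g a [GenotypeData].
#' @param path output path (plain text).
#' @export
writeGenotypesVcf <- function(g, path) {
  v <- variantInfo(g)
  d <- SummarizedExperiment::assay(g, "dosage")  # variants x samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=IS,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t")), con)
  gtCode <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(d))) {
    ds <- d[i, ]
    gt <- ifelse(is.na(ds), "./.", gtCode[round(ds) + 1L])
    dsStr <- ifelse(is.na(ds), ".", formatC(ds, format = "g", digits = 8))
    writeLines(paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i],
                       v$alt[i], ".", "PASS",
                       sprintf("IS=%s", formatC(v$info_score[i], format = "g",
                                                digits = 6)),
                       "GT:DS", paste(gt, dsStr, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes as a dosage-matrix TSV plus a variant-table TSV
#' @param g a [GenotypeData].
#' @param dosagePath,variantPath output paths.
#' @export
writeGenotypeMatrix <- function(g, dosagePath, variantPath) {
  d <- dosages(g)
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, dosagePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(variantInfo(g), variantPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dosagePath)
}

# Exact Hardy-Weinberg test p-value from genotype counts (two-sided,
# conditional on allele counts; enumeration over heterozygote counts).
.hweExactP <- function(nHet, nHom1, nHom2) {
  n <- nHet + nHom1 + nHom2
  nA <- 2 * min(nHom1, nHom2) + nHet      # rarer allele count
  hs <- seq(nA %% 2, nA, by = 2)
  hs <- hs[(nA - hs) / 2 + hs <= n * 2]   # guard (always true)
  na <- 2 * n - nA
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (nA - hs) / 2 - hs) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nHet, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Per-variant quality control
#'
#' Removes variants with minor allele frequency below \code{mafMin} or
#' imputation info score below \code{infoMin} (both strict \code{<}, so
#' boundary values are retained), with missingness above \code{missMax}, or
#' failing an exact Hardy-Weinberg test at \code{hwePMin} (applied only when
#' all observed dosages are integer). The filter is idempotent.
#'
#' @param g a [GenotypeData].
#' @param mafMin,infoMin strict lower thresholds in [0,1].
#' @param missMax maximum tolerated per-variant missing fraction.
#' @param hwePMin exact-test p-value cutoff; 0 disables the check.
#' @return filtered [GenotypeData] with an attribute-like
#'   \code{metadata()$qcReport} data.frame of removal counts by reason.
#' @export
applyVariantQC <- function(g, mafMin = 0.05, infoMin = 0.3,
                           missMax = 0.05, hwePMin = 1e-6) {
  stopifnot(mafMin >= 0, mafMin <= 1, infoMin >= 0, infoMin <= 1)
  v <- variantInfo(g)
  d <- dosages(g)
  missFrac <- colMeans(is.na(d))
  badMaf <- v$maf < mafMin
  badInfo <- v$info_score < infoMin
  badMiss <- missFrac > missMax
  intMode <- all(d[!is.na(d)] == round(d[!is.na(d)]))
  badHwe <- rep(FALSE, ncol(d))
  if (hwePMin > 0 && intMode) {
    badHwe <- vapply(seq_len(ncol(d)), function(j) {
      x <- d[, j]; x <- x[!is.na(x)]
      cnt <- tabulate(x + 1L, nbins = 3L)
      .hweExactP(cnt[2], cnt[1], cnt[3]) < hwePMin
    }, logical(1))
  }
  drop <- badMaf | badInfo | badMiss | badHwe
  if (all(drop)) stop("QC removed every variant (empty panel)")
  report <- data.frame(
    reason = c("low_maf", "low_info", "high_missingness", "hwe_failure",
               "retained"),
    n = c(sum(badMaf), sum(badInfo), sum(badMiss), sum(badHwe), sum(!drop)))
  out <- g[!drop, ]
  out <- as(out, "GenotypeData")
  S4Vectors::metadata(out)$qcReport <- report
  out
}

#' Read pathway gene sets (GMT) and gene coordinates (BED)
#'
#' GMT parsing goes through [fgsea::gmtPathways()]; the second GMT column is
#' kept as the pathway id. BED intervals (0-based half-open on disk) are
#' imported with \pkg{rtracklayer} and exposed 1-based inclusive. Genes named
#' in the GMT but absent from the BED are reported as a warning and retained
#' in the pathway definition.
#'
#' @param gmtPath,bedPath input paths.
#' @return list with \code{pathways} (named list of gene-symbol vectors,
#'   names are set names, with an \code{"ids"} attribute) and \code{genes}
#'   (data.frame gene_symbol, chrom, start, end).
#' @export
readGeneSets <- function(gmtPath, bedPath) {
  pw <- fgsea::gmtPathways(gmtPath)
  if (any(lengths(pw) == 0L)) stop("GMT contains an empty pathway")
  dup <- vapply(pw, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate gene symbols within pathway(s): ",
            paste(names(pw)[dup], collapse = ", "), "; deduplicated")
    pw <- lapply(pw, unique)
  }
  fields <- strsplit(readLines(gmtPath), "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 2L)
  names(ids) <- vapply(fields, `[`, character(1), 1L)
  attr(pw, "ids") <- ids[names(pw)]

  bed <- rtracklayer::import(bedPath, format = "bed")
  genes <- data.frame(
    gene_symbol = bed$name,
    chrom = as.character(GenomicRanges::seqnames(bed)),
    start = GenomicRanges::start(bed),  # 1-based inclusive after import
    end = GenomicRanges::end(bed),
    stringsAsFactors = FALSE)
  if (any(genes$start > genes$end)) stop("gene with start > end in BED")

  missing <- setdiff(unique(unlist(pw, use.names = FALSE)), genes$gene_symbol)
  if (length(missing))
    warning(length(missing), " pathway gene(s) absent from the BED ",
            "annotation (retained): ",
            paste(utils::head(missing, 5), collapse = ", "))
  list(pathways = pw, genes = genes)
}

#' Write gene annotation as BED (0-based half-open)
#' @param genes data.frame gene_symbol, chrom, start, end (1-based inclusive).
#' @param path output path.
#' @export
writeGeneBed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    name = genes$gene_symbol)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write pathway gene sets as GMT
#' @param pathways named list of gene-symbol vectors; an optional
#'   \code{"ids"} attribute supplies the description column.
#' @param path output path.
#' @export
writePathwaysGmt <- function(pathways, path) {
  ids <- attr(pathways, "ids")
  if (is.null(ids)) ids <- stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, unname(ids[nm]), pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a phenotype table TSV
#'
#' Columns: sample_id, sex, age, sbp, dbp, on_med (0/1), plus any derived
#' columns already present (raw columns are never overwritten by the
#' phenotype-preparation step, so round-trips are lossless).
#'
#' @param phen phenotype data.frame.
#' @param path file path.
#' @export
writePhenotypeTsv <- function(phen, path) {
  out <- phen
  out$on_med <- as.integer(out$on_med)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTsv
#' @export
readPhenotypeTsv <- function(path) {
  phen <- utils::read.delim(path, stringsAsFactors = FALSE)
  phen$on_med <- phen$on_med == 1 | phen$on_med == "TRUE"
  phen
}

#' Write a complete synthetic study to a directory
#'
#' Emits, per cohort, a VCF (GT + DS) and a phenotype TSV, plus the shared
#' gene BED, pathway GMT and a truth TSV of causal effect sizes.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cohort in c("discovery", "validation", "target")) {
    writeGenotypesVcf(study[[cohort]]$genotypes,
                      file.path(dir, paste0(cohort, ".vcf")))
    writePhenotypeTsv(study[[cohort]]$phenotypes,
                      file.path(dir, paste0(cohort, "_phenotypes.tsv")))
  }
  writeGeneBed(geneAnnotation(study$pool), file.path(dir, "genes.bed"))
  writePathwaysGmt(pathwayDefinitions(study$pool),
                   file.path(dir, "pathways.gmt"))
  utils::write.table(trueEffects(study$pool), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
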