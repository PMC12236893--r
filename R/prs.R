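#' The default p-value threshold grid
#'
#' Seven thresholds at which candidate PRS models are built before
#' validation-based selection.
#' @export
prsThresholds <- function() c(0.0010, 0.0025, 0.0050, 0.0075, 0.0100,
                              0.0250, 0.0500)

#' Map variants to a pathway's genes by coordinates
#'
#' A variant belongs to the pathway iff its position lies within
#' \code{[start - flankBp, end + flankBp]} of some pathway gene (1-based
#' inclusive endpoints; default flank 0).
#'
#' @param variants variant data.frame (variant_id, chrom, pos), e.g. from
#'   [variantInfo()].
#' @param genes gene annotation data.frame (gene_symbol, chrom, start, end).
#' @param pathwayGenes character vector of gene symbols (one pathway).
#' @param flankBp symmetric flank in bp.
#' @return deduplicated character vector of variant ids (panel order); an
#'   empty set triggers a warning.
#' @export
mapSnpsToPathway <- function(variants, genes, pathwayGenes, flankBp = 0) {
  g <- genes[genes$gene_symbol %in% pathwayGenes, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("pathway has no genes in the annotation; empty SNP set")
    return(character(0))
  }
  lv <- union(unique(as.character(variants$chrom)),
              unique(as.character(g$chrom)))
  vr <- GenomicRanges::GRanges(factor(variants$chrom, levels = lv),
                               IRanges::IRanges(variants$pos, width = 1L))
  gr <- GenomicRanges::GRanges(factor(g$chrom, levels = lv),
                               IRanges::IRanges(pmax(1, g$start - flankBp),
                                                g$end + flankBp))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  ids <- unique(variants$variant_id[unique(S4Vectors::queryHits(hits))])
  if (length(ids) == 0L) warning("no variants map to the pathway")
  ids
}

#' Union gene set across pathways
#'
#' @param pathways named list of gene-symbol vectors.
#' @return deduplicated character vector of gene symbols, suitable as the
#'   "combined" pathway.
#' @export
buildCombinedSet <- function(pathways) {
  stopifnot(length(pathways) >= 1L)
  unique(unlist(pathways, use.names = FALSE))
}

#' Threshold clump-retained association results
#'
#' Keeps variants with \code{p_value <= threshold}. Zero survivors are
#' valid (flagged via a message) and produce an empty model downstream.
#'
#' @param assoc association data.frame restricted to clump-retained variants.
#' @param threshold p-value cutoff; must belong to \code{grid}.
#' @param grid allowed thresholds (set to NULL to skip the check).
#' @return the surviving rows of \code{assoc}.
#' @export
thresholdVariants <- function(assoc, threshold, grid = prsThresholds()) {
  if (!is.null(grid) && !any(abs(grid - threshold) < 1e-12))
    stop("threshold ", threshold, " is not in the configured grid")
  out <- assoc[assoc$p_value <= threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    message("no variants pass threshold ", threshold, " (empty model)")
  out
}

#' Assemble a PRS model from clumped, thresholded associations
#'
#' @param assoc association data.frame (oriented: beta >= 0, risk_allele
#'   set) for one trait.
#' @param retained character vector of clump-retained variant ids.
#' @param threshold p-value cutoff from the grid.
#' @param trait,pathwayId labels stored on the model.
#' @param grid allowed thresholds, see [thresholdVariants()].
#' @return a [PRSModel].
#' @export
buildPrsModel <- function(assoc, retained, threshold, trait, pathwayId,
                          grid = prsThresholds()) {
  a <- assoc[assoc$variant_id %in% retained, , drop = FALSE]
  a <- thresholdVariants(a, threshold, grid)
  entries <- data.frame(variant_id = a$variant_id,
                        risk_allele = a$risk_allele,
                        other_allele = a$other_allele,
                        weight = a$beta, p = a$p_value,
                        stringsAsFactors = FALSE)
  new("PRSModel", trait = trait, pathwayId = pathwayId,
      threshold = threshold, entries = entries)
}

#' Score samples with a PRS model
#'
#' Default scoring is the weighted mean risk-allele dosage per allele:
#' \deqn{score_i = \sum_j w_j d_{ij} / (2 m_i)} with \eqn{m_i} the number of
#' non-missing model variants for sample i (\code{missing = "drop"});
#' \code{missing = "meanImpute"} substitutes the variant's mean dosage and
#' keeps the full denominator, and \code{mode = "sum"} drops the
#' denominator entirely. Dosages are flipped to the model's risk allele
#' where the panel's alt allele is the other allele; model variants absent
#' from the panel are dropped with a warning. Samples with zero usable
#' variants get an NA score.
#'
#' @param g a [GenotypeData].
#' @param model a [PRSModel].
#' @param missing "drop" or "meanImpute".
#' @param mode "avg" (per-allele weighted mean) or "sum".
#' @return data.frame: sample_id, score, n_variants_used.
#' @export
scoreSamples <- function(g, model, missing = c("drop", "meanImpute"),
                         mode = c("avg", "sum")) {
  missing <- match.arg(missing)
  mode <- match.arg(mode)
  d <- dosages(g)
  v <- variantInfo(g)
  e <- prsEntries(model)
  n <- nrow(d)
  if (nrow(e) == 0L)
    return(data.frame(sample_id = rownames(d), score = NA_real_,
                      n_variants_used = 0L, stringsAsFactors = FALSE))
  idx <- match(e$variant_id, v$variant_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " model variant(s) absent from genotypes; dropped")
    e <- e[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(e) == 0L)
    return(data.frame(sample_id = rownames(d), score = NA_real_,
                      n_variants_used = 0L, stringsAsFactors = FALSE))
  dm <- d[, idx, drop = FALSE]
  flip <- e$risk_allele == v$ref[idx] & e$other_allele == v$alt[idx]
  aligned <- flip | (e$risk_allele == v$alt[idx] & e$other_allele == v$ref[idx])
  if (!all(aligned)) {
    warning(sum(!aligned), " model variant(s) with unmatched alleles; dropped")
    dm <- dm[, aligned, drop = FALSE]
    e <- e[aligned, , drop = FALSE]
    flip <- flip[aligned]
  }
  if (any(flip)) dm[, flip] <- 2 - dm[, flip, drop = FALSE]
  obs <- !is.na(dm)
  mUsed <- rowSums(obs)
  if (missing == "meanImpute" && any(!obs)) {
    mu <- colMeans(dm, na.rm = TRUE)
    for (j in which(colSums(!obs) > 0)) dm[!obs[, j], j] <- mu[j]
    mUsed <- rep(ncol(dm), n)
  }
  dm0 <- dm; dm0[is.na(dm0)] <- 0
  num <- as.vector(dm0 %*% e$weight)
  score <- switch(mode,
                  avg = ifelse(mUsed > 0, num / (2 * mUsed), NA_real_),
                  sum = ifelse(mUsed > 0, num, NA_real_))
  if (any(mUsed == 0))
    warning(sum(mUsed == 0), " sample(s) with zero usable model variants; NA score")
  data.frame(sample_id = rownames(d), score = score,
             n_variants_used = as.integer(mUsed), stringsAsFactors = FALSE)
}

#' Write a PRS model / profile as TSV
#' @param model a [PRSModel].
#' @param path output path.
#' @export
writePrsModelTsv <- function(model, path) {
  utils::write.table(prsEntries(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePrsModelTsv
#' @param profiles data.frame from [scoreSamples()].
#' @export
writePrsProfileTsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
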