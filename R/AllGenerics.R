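#' Extract the dosage matrix (samples x variants)
#'
#' @param x a [GenotypeData].
#' @return numeric matrix with sample ids as rownames and variant ids as
#'   colnames; values in [0,2] or NA.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Variant metadata table
#'
#' @param x a [GenotypeData] or [HaplotypePool].
#' @return data.frame with variant_id, chrom, pos, ref, alt, maf, info_score.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' Sample identifiers
#' @param x a [GenotypeData].
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' PRS model entries
#' @param x a [PRSModel].
#' @return data.frame variant_id, risk_allele, other_allele, weight, p.
#' @export
setGeneric("prsEntries", function(x) standardGeneric("prsEntries"))

#' Is a PRS model empty (no variant passed the threshold)?
#' @param x a [PRSModel].
#' @export
setGeneric("isEmptyModel", function(x) standardGeneric("isEmptyModel"))

#' Gene annotation of a synthetic study layout
#' @param x a [HaplotypePool].
#' @return data.frame gene_symbol, chrom, start, end (1-based inclusive).
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' Pathway definitions of a synthetic study layout
#' @param x a [HaplotypePool].
#' @return named list of gene-symbol vectors.
#' @export
setGeneric("pathwayDefinitions", function(x) standardGeneric("pathwayDefinitions"))

#' True simulated effect sizes
#' @param x a [HaplotypePool].
#' @return data.frame variant_id, beta_sbp, beta_dbp (causal variants only).
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))

#' Summarize an evaluation report as a one-row data.frame
#' @param x an [EvaluationReport].
#' @param ... unused.
#' @export
setGeneric("reportSummary", function(x, ...) standardGeneric("reportSummary"))

#' @rdname dosages
setMethod("dosages", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname variantInfo
setMethod("variantInfo", "GenotypeData", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  rr <- SummarizedExperiment::rowRanges(x)
  df <- data.frame(
    variant_id = rd$variant_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = rd$ref, alt = rd$alt, maf = rd$maf,
    info_score = rd$info_score,
    stringsAsFactors = FALSE
  )
  if ("block" %in% colnames(rd)) df$block <- rd$block
  rownames(df) <- NULL
  df
})

#' @rdname variantInfo
setMethod("variantInfo", "HaplotypePool", function(x) x@variants)

#' @rdname sampleIds
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' @rdname prsEntries
setMethod("prsEntries", "PRSModel", function(x) x@entries)

#' @rdname isEmptyModel
setMethod("isEmptyModel", "PRSModel", function(x) nrow(x@entries) == 0L)

#' @rdname geneAnnotation
setMethod("geneAnnotation", "HaplotypePool", function(x) x@genes)

#' @rdname pathwayDefinitions
setMethod("pathwayDefinitions", "HaplotypePool", function(x) x@pathways)

#' @rdname trueEffects
setMethod("trueEffects", "HaplotypePool", function(x) x@truth)

#' @rdname reportSummary
setMethod("reportSummary", "EvaluationReport", function(x, ...) {
  data.frame(
    trait = x@trait, pathway_id = x@pathwayId,
    chosen_threshold = x@chosenThreshold, n_snps = x@nSnps,
    r2_base = x@r2Base, r2_full = x@r2Full,
    r2_increment = x@r2Increment,
    r2_increment_rel = if (is.na(x@r2Increment) || x@r2Base <= 0) NA_real_ else
      x@r2Increment / x@r2Base,
    increment_p = x@incrementP,
    t_extreme = if (nrow(x@extremeComparison)) x@extremeComparison$t_stat else NA_real_,
    p_extreme = if (nrow(x@extremeComparison)) x@extremeComparison$p_value else NA_real_,
    cohens_d = if (nrow(x@extremeComparison)) x@extremeComparison$cohens_d else NA_real_,
    auc = x@auc,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohorts: discovery %d / validation %d / target %d\n",
              object@nDiscovery, object@nValidation, object@nTarget))
  cat(sprintf("  panel: %d blocks x %d SNPs, within-block r2 = %.3g, MAF in [%.3g, %.3g]\n",
              object@nBlocks, object@snpsPerBlock, object@withinBlockR2,
              object@mafRange[1], object@mafRange[2]))
  cat(sprintf("  layout: %d genes/block, %d pathways, causal: %s\n",
              object@genesPerBlock, object@nPathways,
              paste(object@causalPathways, collapse = ", ")))
  cat(sprintf("  genetics: h2 = %.3g; SBP %g (%g), DBP %g (%g), noise cor %.2f\n",
              object@h2Prs, object@sbpMean, object@sbpSd,
              object@dbpMean, object@dbpSd, object@bpNoiseCor))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "HaplotypePool", function(object) {
  cat(sprintf("HaplotypePool: %d variants in %d blocks, %d genes, %d pathways\n",
              nrow(object@variants), length(object@blocks),
              nrow(object@genes), length(object@pathways)))
  cat(sprintf("  coupling lambda = %.4g (target within-block r2 = %.4g)\n",
              object@lambda, object@config@withinBlockR2))
  cat(sprintf("  causal variants with recorded effects: %d\n", nrow(object@truth)))
})

setMethod("show", "PRSModel", function(object) {
  cat(sprintf("PRSModel: trait %s, pathway %s, threshold p <= %g\n",
              object@trait, object@pathwayId, object@threshold))
  cat(sprintf("  %d weighted risk-allele entries%s\n", nrow(object@entries),
              if (nrow(object@entries) == 0L) " (empty model)" else ""))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %s / %s (threshold %g, %d SNPs)\n",
              object@trait, object@pathwayId, object@chosenThreshold,
              object@nSnps))
  cat(sprintf("  R2 base %.4f -> full %.4f (increment %.4f, p = %.3g)\n",
              object@r2Base, object@r2Full, object@r2Increment,
              object@incrementP))
  ec <- object@extremeComparison
  if (nrow(ec))
    cat(sprintf("  deciles 1 vs 10: t = %.3f, p = %.3g, Cohen's d = %.2f\n",
                ec$t_stat, ec$p_value, ec$cohens_d))
  cat(sprintf("  hypertension AUC = %.3f\n", object@auc))
})
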