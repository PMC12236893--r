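#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom withr with_seed
#' @importFrom stats lm pt plogis rnorm rbinom runif sd var cor t.test prcomp
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Simulation configuration for a synthetic three-cohort PRS study
#'
#' Holds every parameter of the synthetic study generator: cohort sizes,
#' LD-block layout, allele-frequency range, gene/pathway layout, the additive
#' genetic architecture, covariate effects, the blood-pressure noise model,
#' and the medication-assignment rule.
#'
#' Within each LD block all SNPs share one minor allele frequency drawn from
#' \code{mafRange}, and haplotypes are a mixture of a fully coupled component
#' and an independent component with mixture weight
#' \code{sqrt(withinBlockR2)}, so that every within-block SNP pair has
#' closed-form LD r-squared equal to \code{withinBlockR2}.
#'
#' @slot nDiscovery,nValidation,nTarget integer cohort sizes.
#' @slot nBlocks,snpsPerBlock integer LD-block layout (snpsPerBlock <= 12 so
#'   block haplotype sets stay enumerable).
#' @slot withinBlockR2 target pairwise LD r-squared within a block, in [0,1].
#' @slot mafRange length-2 numeric, per-block MAF range within (0, 0.5].
#' @slot genesPerBlock integer genes tiling each block.
#' @slot nPathways integer number of synthetic pathways; genes are assigned
#'   round-robin so every pathway spans many blocks.
#' @slot causalPathways character ids of pathways whose mapped SNPs carry
#'   additive effects.
#' @slot h2Prs fraction of (medication-adjusted) trait variance explained by
#'   the causal genetic score, in [0,1).
#' @slot covariateEffects named list: \code{age} (mmHg/year), \code{sex_male}
#'   (mmHg), \code{pc} (numeric vector of latent-ancestry effects, may be
#'   empty).
#' @slot sexMaleProb probability a sample is male.
#' @slot sbpMean,sbpSd,dbpMean,dbpSd target trait scales (mmHg).
#' @slot bpNoiseCor correlation of the SBP/DBP residual noise pair.
#' @slot medParams named numeric \code{c(midpoint, scale, max)} of the capped
#'   logistic that maps latent (pre-noise) SBP to medication probability.
#' @slot treatmentEffect named numeric \code{c(sbp, dbp)}: mmHg subtracted
#'   from measured BP for treated samples.
#' @slot imputationNoise logical; if TRUE cohort dosages get bounded
#'   beta-distributed jitter in [0,2] instead of staying integer.
#' @slot seed integer master seed for the study layout and effect draws.
#'
#' @seealso [simulationConfig()] for the user-facing constructor.
#' @export
setClass("SimulationConfig",
  representation(
    nDiscovery = "integer", nValidation = "integer", nTarget = "integer",
    nBlocks = "integer", snpsPerBlock = "integer",
    withinBlockR2 = "numeric", mafRange = "numeric",
    genesPerBlock = "integer", nPathways = "integer",
    causalPathways = "character",
    h2Prs = "numeric", covariateEffects = "list", sexMaleProb = "numeric",
    sbpMean = "numeric", sbpSd = "numeric",
    dbpMean = "numeric", dbpSd = "numeric", bpNoiseCor = "numeric",
    medParams = "numeric", treatmentEffect = "numeric",
    imputationNoise = "logical", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(object@nDiscovery, object@nValidation, object@nTarget,
           object@nBlocks, object@snpsPerBlock, object@genesPerBlock,
           object@nPathways)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@snpsPerBlock > 12L)
    msg <- c(msg, "snpsPerBlock must be <= 12 (block haplotypes are enumerated)")
  if (object@withinBlockR2 < 0 || object@withinBlockR2 > 1)
    msg <- c(msg, "withinBlockR2 must lie in [0, 1]")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing interval within (0, 0.5]")
  if (object@h2Prs < 0 || object@h2Prs >= 1)
    msg <- c(msg, "h2Prs must lie in [0, 1)")
  if (object@genesPerBlock > object@snpsPerBlock)
    msg <- c(msg, "genesPerBlock cannot exceed snpsPerBlock")
  if (!all(c("age", "sex_male", "pc") %in% names(object@covariateEffects)))
    msg <- c(msg, "covariateEffects needs elements 'age', 'sex_male', 'pc'")
  if (object@bpNoiseCor <= -1 || object@bpNoiseCor >= 1)
    msg <- c(msg, "bpNoiseCor must lie in (-1, 1)")
  if (!all(c("midpoint", "scale", "max") %in% names(object@medParams)) ||
      object@medParams[["max"]] < 0 || object@medParams[["max"]] > 1)
    msg <- c(msg, "medParams needs midpoint/scale/max with max in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Per-block haplotype pool for the synthetic genotype model
#'
#' Explicit haplotype sets (patterns x frequencies) per LD block, together
#' with the variant table and the gene/pathway layout derived from one
#' [SimulationConfig]. Frequencies within a block sum to one, so cohorts are
#' simulated by drawing two haplotypes per sample per block and summing.
#'
#' @slot variants data.frame: variant_id, chrom, pos, ref, alt, maf, block.
#' @slot blocks list, one element per block: \code{haps} (0/1 matrix of
#'   distinct haplotypes) and \code{freq} (their frequencies).
#' @slot lambda coupling weight \code{sqrt(withinBlockR2)}.
#' @slot genes data.frame gene annotation: gene_symbol, chrom, start, end.
#' @slot pathways named list of gene-symbol vectors.
#' @slot truth data.frame of true additive effects (variant_id, beta_sbp,
#'   beta_dbp) on causal variants; zero rows when h2Prs = 0.
#' @slot config the generating [SimulationConfig].
#' @export
setClass("HaplotypePool",
  representation(
    variants = "data.frame", blocks = "list", lambda = "numeric",
    genes = "data.frame", pathways = "list", truth = "data.frame",
    config = "SimulationConfig"
  )
)

setValidity("HaplotypePool", function(object) {
  msg <- character()
  for (b in seq_along(object@blocks)) {
    blk <- object@blocks[[b]]
    if (abs(sum(blk$freq) - 1) > 1e-12)
      msg <- c(msg, sprintf("block %d haplotype frequencies do not sum to 1", b))
    if (any(blk$freq < 0))
      msg <- c(msg, sprintf("block %d has negative haplotype frequencies", b))
  }
  rng <- object@config@mafRange
  if (any(object@variants$maf < rng[1] - 1e-12 |
          object@variants$maf > rng[2] + 1e-12))
    msg <- c(msg, "realized MAFs fall outside mafRange")
  if (length(msg)) msg else TRUE
})

#' Dosage genotype container
#'
#' A thin [SummarizedExperiment::RangedSummarizedExperiment] subclass holding
#' one \code{"dosage"} assay (variants in rows, samples in columns, values in
#' [0,2] or NA) with variant metadata (variant_id, ref, alt, maf, info_score)
#' in \code{rowData} and genomic positions in \code{rowRanges}.
#'
#' Use [dosages()] to obtain the samples x variants numeric matrix most
#' downstream computations operate on, and [variantInfo()] / [sampleIds()]
#' for the metadata.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  need <- c("variant_id", "ref", "alt", "maf", "info_score")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    msg <- c(msg, paste("rowData lacks columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Threshold-selected PRS model
#'
#' The product of clumping and thresholding for one trait and one pathway
#' (or the combined pathway union): the retained variants with their oriented
#' risk alleles and non-negative weights (discovery-cohort effect sizes).
#'
#' @slot trait one of "SBP", "DBP", "MAP", "PP".
#' @slot pathwayId pathway identifier or "combined".
#' @slot threshold the p-value cutoff the entries passed.
#' @slot entries data.frame: variant_id, risk_allele, other_allele, weight, p.
#'   May have zero rows (a valid empty model, flagged by [isEmptyModel()]).
#' @export
setClass("PRSModel",
  representation(trait = "character", pathwayId = "character",
                 threshold = "numeric", entries = "data.frame")
)

setValidity("PRSModel", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("variant_id", "risk_allele", "other_allele", "weight", "p")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, paste("entries needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(e) && any(e$weight < 0))
      msg <- c(msg, "weights must be non-negative after risk-allele orientation")
    if (nrow(e) && any(e$p > object@threshold + 1e-15))
      msg <- c(msg, "entries contain p-values above the model threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Target-cohort evaluation report for one trait x pathway PRS
#'
#' @slot trait,pathwayId what was evaluated.
#' @slot chosenThreshold validation-selected p-value threshold.
#' @slot r2Base,r2Full,r2Increment,incrementP nested-model R-squared and the
#'   two-sided p-value of the PRS coefficient in the full model.
#' @slot nSnps number of SNPs in the evaluated model.
#' @slot decileTable data.frame decile, n, mean, sd of the trait by PRS decile.
#' @slot extremeComparison one-row data.frame from [compareExtremeDeciles()].
#' @slot auc rank-based AUC of the PRS for hypertension status (NA when a
#'   class is absent or the model is empty).
#' @export
setClass("EvaluationReport",
  representation(trait = "character", pathwayId = "character",
                 chosenThreshold = "numeric",
                 r2Base = "numeric", r2Full = "numeric",
                 r2Increment = "numeric", incrementP = "numeric",
                 nSnps = "integer", decileTable = "data.frame",
                 extremeComparison = "data.frame", auc = "numeric")
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!is.na(object@r2Increment) && object@r2Increment < -1e-12)
    msg <- c(msg, "r2Increment must be >= 0 (nested OLS)")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
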