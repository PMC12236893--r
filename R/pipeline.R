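#' Full clumping-and-thresholding PRS pipeline
#'
#' Orchestrates, per trait and per pathway (plus the combined union of all
#' pathway genes): discovery-cohort GWAS over the pathway-mapped SNP union,
#' greedy LD clumping, candidate PRS models at the seven-threshold grid,
#' validation-cohort threshold selection by maximal incremental R-squared,
#' and target-cohort evaluation (incremental R-squared, decile
#' stratification, extreme-decile t-test, hypertension AUC). The variant
#' panels of the three cohorts are intersected first; ancestry PCs are
#' computed per cohort on the full intersected panel. The run is fully
#' deterministic: identical inputs give identical outputs.
#'
#' @param discovery,validation,target cohort bundles: each a list with
#'   \code{genotypes} ([GenotypeData]) and \code{phenotypes} (data.frame,
#'   prepared with [preparePhenotypes()] or raw, in which case it is
#'   prepared here).
#' @param pathways named list of gene-symbol vectors.
#' @param genes gene annotation data.frame (gene_symbol, chrom, start, end).
#' @param traits subset of c("SBP","DBP","MAP","PP").
#' @param thresholds p-value grid, default [prsThresholds()].
#' @param clump [clumpParams()].
#' @param nPcs ancestry PCs per cohort.
#' @param includeCombined evaluate the combined pathway union.
#' @param perPathway evaluate each individual pathway.
#' @param ldMethod "em" (maximum-likelihood haplotype r2) or "dosage".
#' @param outDir optional directory; when given, association tables, clump
#'   reports, model and profile TSVs and the report summary are persisted.
#' @return list: \code{reports} (named list of [EvaluationReport], keys
#'   "TRAIT.pathway"), \code{summary} (one row per report),
#'   \code{correlations} (per trait, pathway-PRS correlation matrix on the
#'   target cohort), \code{panel} (variant intersection bookkeeping),
#'   \code{intermediates} (associations, clump results, validation
#'   increments, chosen models, target profiles).
#' @export
runPipeline <- function(discovery, validation, target, pathways, genes,
                        traits = c("SBP", "DBP", "MAP", "PP"),
                        thresholds = prsThresholds(),
                        clump = clumpParams(), nPcs = 5,
                        includeCombined = TRUE, perPathway = TRUE,
                        ldMethod = c("em", "dosage"), outDir = NULL) {
  ldMethod <- match.arg(ldMethod)
  traits <- match.arg(traits, several.ok = TRUE)
  cohorts <- list(discovery = discovery, validation = validation,
                  target = target)

  ids <- Reduce(intersect, lapply(cohorts, function(co)
    variantInfo(co$genotypes)$variant_id))
  if (length(ids) == 0L) stop("no variants shared across the three cohorts")
  panel <- data.frame(
    cohort = names(cohorts),
    n_variants = vapply(cohorts, function(co)
      nrow(variantInfo(co$genotypes)), integer(1)),
    n_dropped = vapply(cohorts, function(co)
      nrow(variantInfo(co$genotypes)) - length(ids), integer(1)))
  for (nm in names(cohorts)) {
    g <- cohorts[[nm]]$genotypes
    sel <- match(ids, variantInfo(g)$variant_id)
    cohorts[[nm]]$genotypes <- as(g[sel, ], "GenotypeData")
    if (!"sbp_adj" %in% colnames(cohorts[[nm]]$phenotypes))
      cohorts[[nm]]$phenotypes <- preparePhenotypes(cohorts[[nm]]$phenotypes)
  }
  pcs <- lapply(cohorts, function(co)
    if (nPcs > 0) computePCs(co$genotypes, k = nPcs) else NULL)

  sets <- list()
  if (perPathway) sets <- c(sets, pathways)
  if (includeCombined) sets$combined <- buildCombinedSet(pathways)
  vInfo <- variantInfo(cohorts$discovery$genotypes)
  snpSets <- lapply(sets, function(gs)
    mapSnpsToPathway(vInfo, genes, gs))
  unionSnps <- unique(unlist(snpSets, use.names = FALSE))
  if (length(unionSnps) == 0L) stop("no variants map to any pathway gene")

  subsetG <- function(g, keepIds) {
    as(g[match(keepIds, variantInfo(g)$variant_id), ], "GenotypeData")
  }
  gDisc <- subsetG(cohorts$discovery$genotypes, unionSnps)

  reports <- list()
  correlations <- list()
  intermediates <- list(associations = list(), clumps = list(),
                        validationIncrements = list(), models = list(),
                        targetProfiles = list())

  for (tr in traits) {
    assoc <- runGwas(gDisc, cohorts$discovery$phenotypes, trait = tr,
                     pcs = pcs$discovery[rownames(dosages(gDisc)), ,
                                         drop = FALSE])
    intermediates$associations[[tr]] <- assoc
    pwScores <- list()
    for (pw in names(snpSets)) {
      aPw <- assoc[assoc$variant_id %in% snpSets[[pw]], , drop = FALSE]
      key <- paste(tr, pw, sep = ".")
      cl <- greedyClump(aPw, cohorts$discovery$genotypes, params = clump,
                        method = ldMethod)
      intermediates$clumps[[key]] <- cl

      inc <- vapply(thresholds, function(th) {
        m <- suppressMessages(
          buildPrsModel(aPw, cl$index, th, tr, pw, grid = thresholds))
        if (isEmptyModel(m)) return(NA_real_)
        sc <- scoreSamples(cohorts$validation$genotypes, m)
        ph <- cohorts$validation$phenotypes
        i <- match(sc$sample_id, ph$sample_id)
        incrementalR2(.traitVector(ph[i, , drop = FALSE], tr), sc$score,
                      .covariateMatrix(ph[i, , drop = FALSE],
                                       pcs$validation))$r2_increment
      }, numeric(1))
      names(inc) <- format(thresholds, trim = TRUE)
      intermediates$validationIncrements[[key]] <- inc
      chosen <- selectBestThreshold(inc)

      model <- suppressMessages(
        buildPrsModel(aPw, cl$index, chosen, tr, pw, grid = thresholds))
      intermediates$models[[key]] <- model
      scT <- suppressWarnings(scoreSamples(cohorts$target$genotypes, model))
      intermediates$targetProfiles[[key]] <- scT
      pwScores[[pw]] <- scT$score
      reports[[key]] <- .evaluateOnTarget(model, scT,
                                          cohorts$target$phenotypes,
                                          pcs$target, tr, pw, chosen)
    }
    if (perPathway && length(pathways) > 1L) {
      m <- do.call(cbind, pwScores[names(pathways)])
      colnames(m) <- names(pathways)
      correlations[[tr]] <- suppressWarnings(pathwayPrsCorrelation(m))
    }
  }

  res <- list(reports = reports,
              summary = do.call(rbind, lapply(reports, reportSummary)),
              correlations = correlations, panel = panel,
              intermediates = intermediates)
  if (!is.null(outDir)) .persistPipeline(res, outDir)
  res
}

# Target-cohort evaluation of one chosen model; degenerate cases (empty
# model, unscoreable samples, single-class hypertension) yield NA metrics
# rather than failures.
.evaluateOnTarget <- function(model, profiles, phen, pcs, trait, pathwayId,
                              chosen) {
  i <- match(profiles$sample_id, phen$sample_id)
  ph <- phen[i, , drop = FALSE]
  y <- .traitVector(ph, trait)
  X <- .covariateMatrix(ph, pcs)
  emptyCmp <- data.frame(n1 = integer(0))
  if (isEmptyModel(model) || all(is.na(profiles$score)) ||
      length(unique(profiles$score[!is.na(profiles$score)])) < 2L) {
    base <- stats::lm(y ~ X)
    r2b <- 1 - sum(stats::residuals(base)^2) / sum((y - mean(y))^2)
    return(new("EvaluationReport", trait = trait, pathwayId = pathwayId,
               chosenThreshold = chosen, r2Base = r2b, r2Full = r2b,
               r2Increment = 0, incrementP = NA_real_,
               nSnps = nrow(prsEntries(model)),
               decileTable = data.frame(),
               extremeComparison = emptyCmp, auc = NA_real_))
  }
  inc <- incrementalR2(y, profiles$score, X)
  dec <- decileStratify(profiles, phen, trait)
  asg <- attr(dec, "assignment")
  yAll <- .traitVector(ph, trait)
  names(yAll) <- ph$sample_id
  cmp <- compareExtremeDeciles(yAll[asg$sample_id[asg$decile == 1]],
                               yAll[asg$sample_id[asg$decile == 10]])
  auc <- tryCatch(aucRank(profiles$score, ph$hypertensive),
                  error = function(e) NA_real_)
  new("EvaluationReport", trait = trait, pathwayId = pathwayId,
      chosenThreshold = chosen, r2Base = inc$r2_base, r2Full = inc$r2_full,
      r2Increment = inc$r2_increment, incrementP = inc$increment_p,
      nSnps = nrow(prsEntries(model)), decileTable = dec,
      extremeComparison = cmp, auc = auc)
}

# Persist pipeline intermediates and the summary as TSVs (deterministic
# content, no timestamps, so identical runs give identical files).
.persistPipeline <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$summary, file.path(outDir, "report_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$panel, file.path(outDir, "variant_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in names(res$intermediates$associations))
    utils::write.table(res$intermediates$associations[[tr]],
                       file.path(outDir, sprintf("assoc_%s.tsv", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(res$intermediates$models)) {
    writePrsModelTsv(res$intermediates$models[[key]],
                     file.path(outDir, sprintf("model_%s.tsv", key)))
    writePrsProfileTsv(res$intermediates$targetProfiles[[key]],
                       file.path(outDir, sprintf("profile_%s.tsv", key)))
    writeClumpReport(res$intermediates$clumps[[key]],
                     res$intermediates$associations[[sub("\\..*$", "", key)]],
                     file.path(outDir, sprintf("clump_%s.tsv", key)))
  }
  for (tr in names(res$correlations))
    utils::write.table(res$correlations[[tr]],
                       file.path(outDir, sprintf("pathway_cor_%s.tsv", tr)),
                       sep = "\t", quote = FALSE)
  dec <- lapply(names(res$reports), function(k) {
    dt <- res$reports[[k]]@decileTable
    if (nrow(dt)) cbind(report = k, dt) else NULL
  })
  dec <- do.call(rbind, dec)
  if (!is.null(dec))
    utils::write.table(dec, file.path(outDir, "decile_tables.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}

#' Run the pipeline directly on a simulated study
#'
#' Convenience wrapper feeding [runPipeline()] the cohorts, gene annotation
#' and pathway definitions of a [simulateStudy()] result.
#'
#' @param study result of [simulateStudy()].
#' @param ... passed to [runPipeline()].
#' @export
runStudyPipeline <- function(study, ...) {
  runPipeline(study$discovery, study$validation, study$target,
              pathways = pathwayDefinitions(study$pool),
              genes = geneAnnotation(study$pool), ...)
}
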