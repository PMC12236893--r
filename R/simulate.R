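#' Create a simulation configuration
#'
#' Constructor for [SimulationConfig]. Defaults mirror the study design the
#' package targets: three non-overlapping cohorts of 2295 / 1614 / 966
#' samples, a variant panel of 22 LD blocks of 10 SNPs, 11 pathways of ~10
#' genes each with one causal pathway, SBP ~ 150 (30) mmHg and DBP ~ 95 (19)
#' mmHg, and a medication flag that is a capped logistic function of latent
#' blood pressure with an exact -15/-10 mmHg treatment effect.
#'
#' @param nDiscovery,nValidation,nTarget cohort sizes.
#' @param nBlocks,snpsPerBlock LD-block layout of the shared variant panel.
#' @param withinBlockR2 target pairwise r2 inside a block (exact, by
#'   construction, because all SNPs in a block share one MAF).
#' @param mafRange interval the per-block MAF is drawn from.
#' @param genesPerBlock genes tiling each block's SNP span.
#' @param nPathways number of pathways; genes are dealt round-robin.
#' @param causalPathways ids (\code{"pathway_01"}...) carrying effects.
#' @param h2Prs variance fraction of the causal score in the
#'   medication-adjusted trait.
#' @param covariateEffects list with \code{age} (mmHg/year), \code{sex_male}
#'   (mmHg) and \code{pc} (vector, latent ancestry axes) coefficients.
#' @param sexMaleProb probability of male sex.
#' @param sbpMean,sbpSd,dbpMean,dbpSd trait scales in mmHg.
#' @param bpNoiseCor residual SBP-DBP noise correlation.
#' @param medParams capped logistic \code{c(midpoint, scale, max)} for the
#'   medication probability given latent (pre-noise) SBP.
#' @param treatmentEffect mmHg subtracted from measured \code{c(sbp, dbp)}
#'   for treated samples.
#' @param imputationNoise add bounded beta-distributed jitter to dosages.
#' @param seed master seed fixing the layout, MAFs and causal effects.
#' @return a validated [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(nDiscovery = 200, nValidation = 100, nTarget = 100,
#'                         nBlocks = 4, snpsPerBlock = 5, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nDiscovery = 2295L, nValidation = 1614L,
                             nTarget = 966L,
                             nBlocks = 22L, snpsPerBlock = 10L,
                             withinBlockR2 = 0.5, mafRange = c(0.05, 0.5),
                             genesPerBlock = 5L, nPathways = 11L,
                             causalPathways = "pathway_01",
                             h2Prs = 0.15,
                             covariateEffects = list(age = 0.5,
                                                     sex_male = 3,
                                                     pc = numeric(0)),
                             sexMaleProb = 0.3,
                             sbpMean = 150, sbpSd = 30,
                             dbpMean = 95, dbpSd = 19,
                             bpNoiseCor = 0.6,
                             medParams = c(midpoint = 165, scale = 8,
                                           max = 0.8),
                             treatmentEffect = c(sbp = 15, dbp = 10),
                             imputationNoise = FALSE, seed = 1L) {
  new("SimulationConfig",
      nDiscovery = as.integer(nDiscovery),
      nValidation = as.integer(nValidation), nTarget = as.integer(nTarget),
      nBlocks = as.integer(nBlocks), snpsPerBlock = as.integer(snpsPerBlock),
      withinBlockR2 = withinBlockR2, mafRange = mafRange,
      genesPerBlock = as.integer(genesPerBlock),
      nPathways = as.integer(nPathways), causalPathways = causalPathways,
      h2Prs = h2Prs, covariateEffects = covariateEffects,
      sexMaleProb = sexMaleProb,
      sbpMean = sbpMean, sbpSd = sbpSd, dbpMean = dbpMean, dbpSd = dbpSd,
      bpNoiseCor = bpNoiseCor, medParams = medParams,
      treatmentEffect = treatmentEffect,
      imputationNoise = imputationNoise, seed = as.integer(seed))
}

# Deterministic study layout: variant panel, gene tiling, pathway assignment.
# All randomness (per-block MAFs, raw causal effects) is drawn under the
# config seed so three cohorts built from the same config share one truth.
.studyLayout <- function(config) {
  nb <- config@nBlocks
  m <- config@snpsPerBlock
  chrom <- as.character(((seq_len(nb) - 1L) %% 22L) + 1L)
  tier <- (seq_len(nb) - 1L) %/% 22L
  blockStart <- 1e6 + tier * 2e6
  spacing <- 2000L

  mafs <- withr::with_seed(config@seed,
    stats::runif(nb, config@mafRange[1], config@mafRange[2]))

  variants <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(
      variant_id = sprintf("var%04d", (b - 1L) * m + seq_len(m)),
      chrom = chrom[b],
      pos = as.integer(blockStart[b] + (seq_len(m) - 1L) * spacing),
      ref = "A", alt = "G",
      maf = mafs[b], block = b,
      stringsAsFactors = FALSE)
  }))

  gpb <- config@genesPerBlock
  genes <- do.call(rbind, lapply(seq_len(nb), function(b) {
    grp <- ceiling(seq_len(m) * gpb / m)  # consecutive groups, sizes differ <= 1
    pos <- variants$pos[variants$block == b]
    do.call(rbind, lapply(seq_len(gpb), function(k) {
      p <- pos[grp == k]
      data.frame(
        gene_symbol = sprintf("GENE%04d", (b - 1L) * gpb + k),
        chrom = chrom[b],
        start = as.integer(min(p) - 500L), end = as.integer(max(p) + 500L),
        stringsAsFactors = FALSE)
    }))
  }))

  ids <- sprintf("pathway_%02d", seq_len(config@nPathways))
  pw <- ((seq_len(nrow(genes)) - 1L) %% config@nPathways) + 1L
  pathways <- lapply(seq_len(config@nPathways),
                     function(i) genes$gene_symbol[pw == i])
  names(pathways) <- ids

  list(variants = variants, genes = genes, pathways = pathways, mafs = mafs)
}

# SNP ids falling inside the genes of the given pathways (coordinate overlap,
# inclusive endpoints), computed on the layout tables.
.layoutPathwaySnps <- function(layout, pathwayIds) {
  gs <- unique(unlist(layout$pathways[pathwayIds], use.names = FALSE))
  g <- layout$genes[layout$genes$gene_symbol %in% gs, , drop = FALSE]
  v <- layout$variants
  hit <- vapply(seq_len(nrow(v)), function(i) {
    any(g$chrom == v$chrom[i] & g$start <= v$pos[i] & g$end >= v$pos[i])
  }, logical(1))
  v$variant_id[hit]
}

#' Build the haplotype pool for a simulation configuration
#'
#' Enumerates, per LD block, the distinct haplotypes and their frequencies
#' under a coupling-mixture model: with probability \code{lambda =
#' sqrt(withinBlockR2)} a haplotype is fully coupled (all-alt with
#' probability MAF, else all-ref); otherwise alleles are independent
#' Bernoulli(MAF). Every SNP's marginal frequency is the block MAF and every
#' within-block pair has \code{D = lambda * p * (1 - p)}, hence r2 exactly
#' \code{withinBlockR2}; variants in different blocks are independent.
#'
#' Causal effects are drawn here as well (standard normal, then scaled so the
#' causal score's pool variance equals \code{h2Prs * sbpSd^2}), so the truth
#' travels with the pool.
#'
#' @param config a [SimulationConfig].
#' @return a [HaplotypePool].
#' @export
buildHaplotypePool <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  lay <- .studyLayout(config)
  lambda <- sqrt(config@withinBlockR2)
  m <- config@snpsPerBlock

  blocks <- lapply(seq_len(config@nBlocks), function(b) {
    p <- lay$mafs[b]
    haps <- as.matrix(expand.grid(rep(list(0:1), m), KEEP.OUT.ATTRS = FALSE))
    dimnames(haps) <- NULL
    storage.mode(haps) <- "integer"
    k <- rowSums(haps)
    freq <- (1 - lambda) * p^k * (1 - p)^(m - k)
    freq[k == m] <- freq[k == m] + lambda * p
    freq[k == 0] <- freq[k == 0] + lambda * (1 - p)
    keep <- freq > 0
    list(haps = haps[keep, , drop = FALSE], freq = freq[keep])
  })

  causalIds <- if (config@h2Prs > 0)
    .layoutPathwaySnps(lay, config@causalPathways) else character(0)
  if (config@h2Prs > 0 && length(causalIds) == 0L)
    stop("h2Prs > 0 but the causal pathways map to no variants")

  truth <- data.frame(variant_id = causalIds,
                      beta_sbp = numeric(length(causalIds)),
                      beta_dbp = numeric(length(causalIds)),
                      stringsAsFactors = FALSE)
  if (length(causalIds)) {
    betaRaw <- withr::with_seed(config@seed + 1L,
                                stats::rnorm(length(causalIds)))
    v <- lay$variants[match(causalIds, lay$variants$variant_id), ]
    # closed-form variance of the raw causal score under the pool model:
    # per block 2pq * ((1 - lambda) * sum(b^2) + lambda * sum(b)^2)
    varRaw <- 0
    for (b in unique(v$block)) {
      sel <- v$block == b
      p <- lay$mafs[b]
      bb <- betaRaw[sel]
      varRaw <- varRaw +
        2 * p * (1 - p) * ((1 - lambda) * sum(bb^2) + lambda * sum(bb)^2)
    }
    if (varRaw <= 0)
      stop("h2Prs incompatible with available causal variance")
    sc <- sqrt(config@h2Prs * config@sbpSd^2 / varRaw)
    truth$beta_sbp <- sc * betaRaw
    truth$beta_dbp <- truth$beta_sbp * config@dbpSd / config@sbpSd
  }

  new("HaplotypePool", variants = lay$variants, blocks = blocks,
      lambda = lambda, genes = lay$genes, pathways = lay$pathways,
      truth = truth, config = config)
}

#' Closed-form LD r2 between two pool variants
#'
#' Exact \code{D^2 / (pA pa pB pb)} computed from the enumerated haplotype
#' frequencies; 0 for variants in different blocks (independent by
#' construction).
#'
#' @param pool a [HaplotypePool].
#' @param id1,id2 variant ids.
#' @export
poolPairR2 <- function(pool, id1, id2) {
  v <- pool@variants
  i <- match(id1, v$variant_id); j <- match(id2, v$variant_id)
  if (is.na(i) || is.na(j)) stop("unknown variant id")
  if (v$block[i] != v$block[j]) return(0)
  blk <- pool@blocks[[v$block[i]]]
  ci <- which(v$variant_id[v$block == v$block[i]] == id1)
  cj <- which(v$variant_id[v$block == v$block[j]] == id2)
  a1 <- blk$haps[, ci]; a2 <- blk$haps[, cj]
  pA <- sum(blk$freq[a1 == 1]); pB <- sum(blk$freq[a2 == 1])
  pAB <- sum(blk$freq[a1 == 1 & a2 == 1])
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Simulate a genotype cohort from a haplotype pool
#'
#' Draws two haplotypes per sample per block independently from the block's
#' haplotype frequencies and sums them into dosages in \{0,1,2\} (or adds
#' bounded beta jitter when the config requests imputation-style noise).
#'
#' @param pool a [HaplotypePool].
#' @param n number of samples (>= 1).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @param idPrefix prefix for generated sample ids.
#' @return a [GenotypeData] with pool MAFs, block labels and
#'   \code{info_score = 1} in its variant metadata.
#' @export
simulateCohort <- function(pool, n, seed, idPrefix = "S") {
  stopifnot(is(pool, "HaplotypePool"), n >= 1)
  n <- as.integer(n)
  dos <- withr::with_seed(seed, {
    cols <- lapply(pool@blocks, function(blk) {
      k <- length(blk$freq)
      i1 <- sample.int(k, n, replace = TRUE, prob = blk$freq)
      i2 <- sample.int(k, n, replace = TRUE, prob = blk$freq)
      blk$haps[i1, , drop = FALSE] + blk$haps[i2, , drop = FALSE]
    })
    d <- do.call(cbind, cols)
    storage.mode(d) <- "double"
    if (pool@config@imputationNoise) {
      jit <- (stats::rbeta(length(d), 2, 2) * 2 - 1) * 0.1
      d[] <- pmin(2, pmax(0, d + jit))
    }
    d
  })
  rownames(dos) <- sprintf("%s%05d", idPrefix, seq_len(n))
  v <- pool@variants
  v$info_score <- 1
  colnames(dos) <- v$variant_id
  g <- GenotypeData(dos, v)
  S4Vectors::metadata(g)$withinBlockR2 <- pool@config@withinBlockR2
  S4Vectors::metadata(g)$lambda <- pool@lambda
  g
}

#' Simulate blood-pressure phenotypes for a cohort
#'
#' Generates SBP/DBP under the additive model \eqn{y = a + \sum_j \beta_j
#' d_j + c_{age} age + c_{sex} male + \epsilon} with correlated SBP/DBP
#' noise, assigns the anti-hypertensive-medication flag from a capped
#' logistic of latent (pre-noise) SBP, and subtracts the treatment effect
#' (default 15/10 mmHg) from measured BP of treated samples. The causal
#' score's variance fraction of the medication-adjusted trait equals
#' \code{h2Prs} by construction (checked empirically in the test suite).
#'
#' @param genotypes a [GenotypeData] containing all causal variants.
#' @param config the generating [SimulationConfig].
#' @param seed RNG seed for covariates, noise and medication assignment.
#' @param pool optional [HaplotypePool]; rebuilt from \code{config} if
#'   missing (the rebuild is deterministic).
#' @return data.frame with sample_id, sex, age, sbp, dbp, on_med and an
#'   attribute \code{"truth"} (true betas, per-sample genetic scores, latent
#'   and untreated BP) for recovery tests.
#' @export
simulatePhenotypes <- function(genotypes, config, seed, pool = NULL) {
  stopifnot(is(genotypes, "GenotypeData"), is(config, "SimulationConfig"))
  if (is.null(pool)) pool <- buildHaplotypePool(config)
  truth <- pool@truth
  dos <- dosages(genotypes)
  n <- nrow(dos)
  if (nrow(truth)) {
    miss <- setdiff(truth$variant_id, colnames(dos))
    if (length(miss))
      stop("causal variants absent from genotypes: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }

  eff <- config@covariateEffects
  kpc <- length(eff$pc)
  ageSd <- 12

  res <- withr::with_seed(seed, {
    age <- round(pmin(95, pmax(18, stats::rnorm(n, 49, ageSd))), 1)
    male <- stats::rbinom(n, 1, config@sexMaleProb)
    pcs <- if (kpc) matrix(stats::rnorm(n * kpc), n, kpc) else NULL

    gS <- if (nrow(truth))
      as.vector(dos[, truth$variant_id, drop = FALSE] %*% truth$beta_sbp)
    else numeric(n)
    gD <- if (nrow(truth))
      as.vector(dos[, truth$variant_id, drop = FALSE] %*% truth$beta_dbp)
    else numeric(n)

    covS <- eff$age * age + eff$sex_male * male +
      (if (kpc) as.vector(pcs %*% eff$pc) else 0)
    varC <- eff$age^2 * ageSd^2 +
      eff$sex_male^2 * config@sexMaleProb * (1 - config@sexMaleProb) +
      sum(eff$pc^2)
    varEpsS <- config@sbpSd^2 * (1 - config@h2Prs) - varC
    if (varEpsS <= 0)
      stop("h2Prs and covariate effects leave no residual variance for SBP")
    sD <- config@dbpSd / config@sbpSd
    varEpsD <- sD^2 * varEpsS
    rho <- config@bpNoiseCor

    v <- pool@variants
    eG <- if (nrow(truth)) {
      p <- v$maf[match(truth$variant_id, v$variant_id)]
      c(sum(truth$beta_sbp * 2 * p), sum(truth$beta_dbp * 2 * p))
    } else c(0, 0)
    eC <- eff$age * 49 + eff$sex_male * config@sexMaleProb
    latS <- config@sbpMean - eG[1] - eC + gS + covS
    latD <- config@dbpMean - eG[2] - eC * sD + gD + covS * sD

    pMed <- config@medParams[["max"]] *
      stats::plogis((latS - config@medParams[["midpoint"]]) /
                    config@medParams[["scale"]])
    onMed <- stats::rbinom(n, 1, pMed) == 1

    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    tS <- config@treatmentEffect[["sbp"]]; tD <- config@treatmentEffect[["dbp"]]
    mkBp <- function(z1, z2) {
      epsS <- sqrt(varEpsS) * z1
      epsD <- sqrt(varEpsD) * (rho * z1 + sqrt(1 - rho^2) * z2)
      list(sbp = round(latS + epsS - tS * onMed, 1),
           dbp = round(latD + epsD - tD * onMed, 1))
    }
    bp <- mkBp(z1, z2)
    for (it in seq_len(100)) {  # redraw noise where DBP >= SBP (rare tail)
      bad <- which(bp$sbp <= bp$dbp)
      if (!length(bad)) break
      z1[bad] <- stats::rnorm(length(bad)); z2[bad] <- stats::rnorm(length(bad))
      bp <- mkBp(z1, z2)
    }
    still <- bp$sbp <= bp$dbp
    bp$dbp[still] <- bp$sbp[still] - 0.5

    out <- data.frame(
      sample_id = rownames(dos),
      sex = ifelse(male == 1, "male", "female"),
      age = age, sbp = bp$sbp, dbp = bp$dbp, on_med = onMed,
      stringsAsFactors = FALSE)
    if (kpc) {
      colnames(pcs) <- sprintf("latent_pc%d", seq_len(kpc))
      out <- cbind(out, pcs)
    }
    attr(out, "truth") <- list(
      beta = truth, geneticScoreSbp = gS, geneticScoreDbp = gD,
      latentSbp = latS, sbpUntreated = bp$sbp + tS * onMed,
      dbpUntreated = bp$dbp + tD * onMed, h2Prs = config@h2Prs)
    out
  })
  res
}

#' Simulate a full three-cohort study
#'
#' Builds the haplotype pool once (shared variant panel, shared truth) and
#' simulates non-overlapping discovery, validation and target cohorts with
#' distinct sample-id prefixes and seeds derived from the config seed.
#'
#' @param config a [SimulationConfig].
#' @return list with \code{pool} and three cohort bundles, each a list of
#'   \code{genotypes} ([GenotypeData]) and \code{phenotypes} (data.frame).
#' @examples
#' cfg <- simulationConfig(nDiscovery = 120, nValidation = 80, nTarget = 80,
#'                         nBlocks = 4, snpsPerBlock = 4, genesPerBlock = 2,
#'                         nPathways = 4, seed = 3)
#' st <- simulateStudy(cfg)
#' dim(dosages(st$discovery$genotypes))
#' @export
simulateStudy <- function(config) {
  pool <- buildHaplotypePool(config)
  s <- config@seed
  mk <- function(n, seedG, seedP, prefix) {
    g <- simulateCohort(pool, n, seed = seedG, idPrefix = prefix)
    p <- simulatePhenotypes(g, config, seed = seedP, pool = pool)
    list(genotypes = g, phenotypes = p)
  }
  list(pool = pool,
       discovery = mk(config@nDiscovery, s + 11L, s + 21L, "D"),
       validation = mk(config@nValidation, s + 12L, s + 22L, "V"),
       target = mk(config@nTarget, s + 13L, s + 23L, "T"))
}
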