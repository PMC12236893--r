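test_that("principal components are orthogonal and symmetric in samples", {
  set.seed(31)
  dos <- matrix(rbinom(100 * 30, 2, 0.3), 100, 30)
  dos[1, ] <- dos[2, ]  # duplicated samples
  g <- makeGenotypeData(dos)
  pc <- computePCs(g, k = 4, thinR2 = 1)
  expect_equal(unname(pc[1, ]), unname(pc[2, ]))
  cc <- cor(pc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # deterministic sign convention: recomputation is identical
  expect_identical(pc, computePCs(g, k = 4, thinR2 = 1))
})

test_that("zero-variance variants are excluded from PCA with a warning", {
  set.seed(32)
  dos <- cbind(matrix(rbinom(50 * 5, 2, 0.4), 50, 5), rep(1, 50))
  g <- makeGenotypeData(dos)
  expect_warning(pc <- computePCs(g, k = 2, thinR2 = 1), "zero-variance")
  expect_equal(ncol(pc), 2L)
})

test_that("PC1 separates diverged subpopulations", {
  cfgA <- smallConfig(nBlocks = 30L, withinBlockR2 = 0, nPathways = 2L,
                      mafRange = c(0.05, 0.15), h2Prs = 0, seed = 33)
  cfgB <- smallConfig(nBlocks = 30L, withinBlockR2 = 0, nPathways = 2L,
                      mafRange = c(0.35, 0.5), h2Prs = 0, seed = 33)
  dA <- dosages(simulateCohort(buildHaplotypePool(cfgA), 150, seed = 34))
  dB <- dosages(simulateCohort(buildHaplotypePool(cfgB), 150, seed = 35))
  rownames(dB) <- sprintf("B%05d", 1:150)
  g <- makeGenotypeData(rbind(dA, dB))
  pc <- computePCs(g, k = 2)
  grp <- rep(c("A", "B"), each = 150)
  mns <- tapply(pc[, 1], grp, mean)
  pooledSd <- sqrt(mean(tapply(pc[, 1], grp, var)))
  expect_gt(abs(diff(mns)) / pooledSd, 4)
})

test_that("single-SNP fits match the normal-equations oracle exactly", {
  set.seed(36)
  n <- 50
  dos <- rbinom(n, 2, 0.4)
  cov <- cbind(age = rnorm(n, 50, 10), sexm = rbinom(n, 1, 0.5))
  y <- 1.3 * dos + 0.4 * cov[, 1] + rnorm(n, 0, 5)
  fit <- fitSnpAssociation(dos, y, cov)
  orc <- olsOracle(y, cbind(dos, cov))
  expect_equal(fit$beta, abs(orc$beta), tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-10)

  # perfect fit
  y2 <- 2 * dos
  fit2 <- suppressWarnings(fitSnpAssociation(dos, y2))
  expect_equal(fit2$beta, 2, tolerance = 1e-10)
  expect_lt(fit2$p_value, 1e-12)

  expect_error(fitSnpAssociation(rep(1, n), y), "monomorphic")
  expect_error(fitSnpAssociation(dos, y, cbind(cov, cov[, 1])),
               "rank-deficient")
})

test_that("risk-allele orientation makes effects non-negative and is involutive", {
  set.seed(37)
  n <- 80
  dos <- rbinom(n, 2, 0.3)
  y <- -0.8 * dos + rnorm(n, 0, 2)
  fit <- fitSnpAssociation(dos, y, ref = "A", alt = "G")
  expect_gte(fit$beta, 0)
  expect_identical(fit$risk_allele, "A")
  expect_true(fit$flipped)
  # recoding dosage 2 - d with swapped allele labels yields the same result
  fit2 <- fitSnpAssociation(2 - dos, y, ref = "G", alt = "A")
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
  expect_identical(fit2$risk_allele, fit$risk_allele)
})

test_that("the vectorized scan equals per-variant OLS and is shift-invariant", {
  st <- simulateStudy(smallConfig(nDiscovery = 120L, nValidation = 10L,
                                  nTarget = 10L))
  g <- st$discovery$genotypes
  ph <- preparePhenotypes(st$discovery$phenotypes)
  pcs <- computePCs(g, k = 2)
  assoc <- runGwas(g, ph, trait = "SBP", pcs = pcs)
  expect_identical(assoc$variant_id,
                   assoc$variant_id[order(as.numeric(assoc$chrom), assoc$pos)])

  X <- cbind(age = ph$age, sex_male = as.numeric(ph$sex == "male"), pcs)
  for (vid in assoc$variant_id[c(1, 10, 25)]) {
    d <- dosages(g)[, vid]
    ref <- fitSnpAssociation(d, ph$sbp_adj, X)
    row <- assoc[assoc$variant_id == vid, ]
    expect_equal(row$beta, ref$beta, tolerance = 1e-10)
    expect_equal(row$se, ref$se, tolerance = 1e-10)
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-10)
  }

  ph2 <- ph
  ph2$sbp_adj <- ph$sbp_adj + 100
  assoc2 <- runGwas(g, ph2, trait = "SBP", pcs = pcs)
  expect_equal(assoc2$beta, assoc$beta, tolerance = 1e-12)
  expect_equal(assoc2$p_value, assoc$p_value, tolerance = 1e-12)

  # misaligned samples are reported by id
  phBad <- ph[-3, ]
  expect_error(runGwas(g, phBad, trait = "SBP", pcs = pcs), "D00003")
})

test_that("null scans are calibrated at the nominal type-I level", {
  hits <- 0; tests <- 0
  for (s in 1:20) {
    cfg <- smallConfig(nBlocks = 125L, snpsPerBlock = 4L, genesPerBlock = 2L,
                       nPathways = 5L, h2Prs = 0, seed = 500 + s)
    pool <- buildHaplotypePool(cfg)
    g <- simulateCohort(pool, 300, seed = 600 + s)
    ph <- preparePhenotypes(simulatePhenotypes(g, cfg, seed = 700 + s,
                                               pool = pool))
    assoc <- runGwas(g, ph, trait = "SBP", nPcs = 0)
    hits <- hits + sum(assoc$p_value < 0.05)
    tests <- tests + nrow(assoc)
  }
  expect_lt(abs(hits / tests - 0.05), 0.02)
})

test_that("detection rates track the noncentral-t power computation", {
  n <- 2295; maf <- 0.3; beta <- 1.5
  power <- function(sigma) {
    ncp <- beta * sqrt(n * 2 * maf * (1 - maf)) / sigma
    df <- n - 2
    crit <- qt(0.975, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  }
  det <- function(sigma) mean(vapply(1:25, function(s) {
    d <- withr::with_seed(800 + s, rbinom(n, 2, maf))
    y <- withr::with_seed(900 + s, 150 + beta * d + rnorm(n, 0, sigma))
    fitSnpAssociation(d, y)$p_value < 0.05
  }, logical(1)))
  # high-power regime: analytic power > 0.99 and >= 95% of seeds detect
  expect_gt(power(10), 0.99)
  expect_gte(det(10), 0.95)
  # moderate regime: empirical detection tracks the analytic power
  expect_lt(abs(det(29) - power(29)), 0.25)
})
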