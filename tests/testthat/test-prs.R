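test_that("SNP-to-pathway mapping uses inclusive gene coordinates", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                         chrom = "1", pos = c(1000, 1500, 2500, 3000),
                         stringsAsFactors = FALSE)
  genes <- data.frame(gene_symbol = c("G1", "G2", "G3"), chrom = "1",
                      start = c(1000, 2800, 5000), end = c(1600, 3000, 6000),
                      stringsAsFactors = FALSE)
  # boundary positions (gene start v1, gene end v4) included;
  # intergenic v3 (between G1 and G2) excluded
  expect_identical(mapSnpsToPathway(variants, genes, c("G1")), c("v1", "v2"))
  expect_identical(mapSnpsToPathway(variants, genes, c("G2")), "v4")
  expect_identical(mapSnpsToPathway(variants, genes, c("G1", "G2")),
                   c("v1", "v2", "v4"))
  # flank extends the capture leftwards from G3 (5000 - 2500 = 2500)
  expect_identical(mapSnpsToPathway(variants, genes, "G3", flankBp = 2500),
                   c("v3", "v4"))
  expect_warning(expect_length(mapSnpsToPathway(variants, genes, "G3"), 0),
                 "no variants")
  expect_warning(out <- mapSnpsToPathway(variants, genes, "ABSENT"),
                 "no genes")
  expect_length(out, 0)
})

test_that("shared genes appear in both pathways but once in the union", {
  variants <- data.frame(variant_id = sprintf("v%d", 1:6), chrom = "1",
                         pos = c(100, 200, 300, 400, 500, 600),
                         stringsAsFactors = FALSE)
  genes <- data.frame(gene_symbol = c("A", "B", "C"), chrom = "1",
                      start = c(90, 290, 490), end = c(210, 410, 610),
                      stringsAsFactors = FALSE)
  pw <- list(p1 = c("A", "B"), p2 = c("B", "C"))
  s1 <- mapSnpsToPathway(variants, genes, pw$p1)
  s2 <- mapSnpsToPathway(variants, genes, pw$p2)
  expect_true(all(c("v3", "v4") %in% s1) && all(c("v3", "v4") %in% s2))
  comb <- mapSnpsToPathway(variants, genes, buildCombinedSet(pw))
  expect_identical(comb, sprintf("v%d", 1:6))  # deduplicated union
  expect_identical(buildCombinedSet(list(p1 = c("A", "B"))), c("A", "B"))
  expect_setequal(buildCombinedSet(pw), c("A", "B", "C"))
})

test_that("thresholding keeps p <= cutoff and nests across the grid", {
  assoc <- data.frame(variant_id = c("a", "b", "c"),
                      p_value = c(0.001, 0.02, 0.3), stringsAsFactors = FALSE)
  expect_identical(thresholdVariants(assoc, 0.025)$variant_id, c("a", "b"))
  expect_error(thresholdVariants(assoc, 0.2), "grid")
  k1 <- thresholdVariants(assoc, 0.001)$variant_id
  k5 <- thresholdVariants(assoc, 0.05)$variant_id
  expect_true(all(k1 %in% k5))
  expect_message(thresholdVariants(assoc[assoc$p_value > 0.5, ], 0.001),
                 "empty")

  # survivors of a uniform null match the binomial expectation
  pu <- withr::with_seed(81, runif(1154))
  nulls <- data.frame(variant_id = as.character(seq_along(pu)), p_value = pu)
  k <- nrow(thresholdVariants(nulls, 0.05))
  expect_lt(abs(k - 1154 * 0.05), 4 * sqrt(1154 * 0.05 * 0.95))
})

test_that("scoring follows the per-allele weighted-mean convention", {
  dos <- matrix(c(1, 2), nrow = 1)
  g <- makeGenotypeData(dos)
  m <- new("PRSModel", trait = "SBP", pathwayId = "combined", threshold = 0.05,
           entries = data.frame(variant_id = c("v001", "v002"),
                                risk_allele = "G", other_allele = "A",
                                weight = c(0.5, 0.3), p = c(0.01, 0.02),
                                stringsAsFactors = FALSE))
  sc <- scoreSamples(g, m)
  expect_equal(sc$score, (0.5 * 1 + 0.3 * 2) / (2 * 2))  # 0.275
  expect_equal(sc$n_variants_used, 2L)
  expect_equal(scoreSamples(g, m, mode = "sum")$score, 1.1)

  # all-zero weights give all-zero scores
  m0 <- m; m0@entries$weight <- c(0, 0)
  expect_equal(scoreSamples(g, m0)$score, 0)
})

test_that("scores match a per-sample loop oracle under missingness", {
  set.seed(82)
  n <- 100; nv <- 12
  dos <- matrix(rbinom(n * nv, 2, 0.35), n, nv)
  dos[sample(length(dos), 40)] <- NA
  g <- makeGenotypeData(dos)
  v <- variantInfo(g)
  w <- runif(nv, 0, 1)
  flip <- seq_len(nv) %% 3 == 0  # some entries keyed to the ref allele
  m <- new("PRSModel", trait = "SBP", pathwayId = "combined", threshold = 0.05,
           entries = data.frame(
             variant_id = v$variant_id,
             risk_allele = ifelse(flip, v$ref, v$alt),
             other_allele = ifelse(flip, v$alt, v$ref),
             weight = w, p = 0.01, stringsAsFactors = FALSE))
  sc <- scoreSamples(g, m)
  for (i in c(1, 7, 50, 100)) {
    num <- 0; used <- 0
    for (j in seq_len(nv)) {
      dij <- dos[i, j]
      if (is.na(dij)) next
      if (flip[j]) dij <- 2 - dij
      num <- num + w[j] * dij
      used <- used + 1
    }
    expect_equal(sc$score[i], num / (2 * used), tolerance = 1e-12)
    expect_equal(sc$n_variants_used[i], used)
  }
})

test_that("scores are invariant to variant order and strand relabeling", {
  set.seed(83)
  dos <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  g <- makeGenotypeData(dos)
  v <- variantInfo(g)
  m <- new("PRSModel", trait = "SBP", pathwayId = "p", threshold = 0.05,
           entries = data.frame(variant_id = v$variant_id,
                                risk_allele = v$alt, other_allele = v$ref,
                                weight = runif(8), p = 0.01,
                                stringsAsFactors = FALSE))
  base <- scoreSamples(g, m)
  mPerm <- m; mPerm@entries <- m@entries[sample(8), ]
  expect_equal(scoreSamples(g, mPerm)$score, base$score, tolerance = 1e-12)

  # panel recoded to the other allele: dosage 2 - d with swapped ref/alt
  v2 <- v; v2$ref <- v$alt; v2$alt <- v$ref
  g2 <- GenotypeData(2 - dos, v2[, c("variant_id", "chrom", "pos", "ref",
                                     "alt")])
  expect_equal(scoreSamples(g2, m)$score, base$score, tolerance = 1e-12)
})

test_that("model variants absent from the panel are dropped with a warning", {
  set.seed(84)
  dos <- matrix(rbinom(30 * 3, 2, 0.3), 30, 3)
  g <- makeGenotypeData(dos)
  m <- new("PRSModel", trait = "SBP", pathwayId = "p", threshold = 0.05,
           entries = data.frame(variant_id = c("v001", "ghost"),
                                risk_allele = "G", other_allele = "A",
                                weight = c(0.4, 0.9), p = 0.01,
                                stringsAsFactors = FALSE))
  expect_warning(sc <- scoreSamples(g, m), "absent")
  expect_equal(sc$score, dos[, 1] * 0.4 / 2)

  # empty model: NA scores, flagged empty
  mE <- new("PRSModel", trait = "SBP", pathwayId = "p", threshold = 0.001,
            entries = m@entries[0, ])
  expect_true(isEmptyModel(mE))
  expect_true(all(is.na(scoreSamples(g, mE)$score)))
})

test_that("combined-union scores equal deduplicated per-pathway scoring", {
  st <- simulateStudy(smallConfig(nDiscovery = 150L, nValidation = 50L,
                                  nTarget = 50L))
  g <- st$discovery$genotypes
  v <- variantInfo(g)
  genes <- geneAnnotation(st$pool)
  pws <- pathwayDefinitions(st$pool)
  # overlapping pathway pair sharing pathway_01's genes
  pwA <- c(pws$pathway_01, pws$pathway_02)
  pwB <- c(pws$pathway_01, pws$pathway_03)
  sA <- mapSnpsToPathway(v, genes, pwA)
  sB <- mapSnpsToPathway(v, genes, pwB)
  union1 <- mapSnpsToPathway(v, genes,
                             buildCombinedSet(list(a = pwA, b = pwB)))
  expect_setequal(union1, union(sA, sB))
  expect_equal(anyDuplicated(union1), 0L)
})
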