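test_that("incremental R2 is zero for a redundant regressor and matches the oracle", {
  set.seed(91)
  n <- 200
  X <- cbind(age = rnorm(n, 50, 10), sexm = rbinom(n, 1, 0.5),
             pc1 = rnorm(n))
  y <- 120 + 0.4 * X[, 1] + 2 * X[, 2] + rnorm(n, 0, 10)

  # PRS identical to an existing covariate adds nothing
  expect_warning(r0 <- incrementalR2(y, X[, 1], X), "collinear")
  expect_lt(r0$r2_increment, 1e-12)

  # known construction vs projection-matrix oracle
  prs <- rnorm(n)
  y2 <- y + 3 * prs
  r <- incrementalR2(y2, prs, X)
  projR2 <- function(M) {
    H <- M %*% solve(crossprod(M)) %*% t(M)
    yc <- y2 - mean(y2)
    1 - sum(((diag(n) - H) %*% y2)^2) / sum(yc^2)
  }
  expect_equal(r$r2_base, projR2(cbind(1, X)), tolerance = 1e-10)
  expect_equal(r$r2_full, projR2(cbind(1, X, prs)), tolerance = 1e-10)
  expect_gte(r$r2_increment, 0)
  expect_lte(r$r2_base, r$r2_full)

  expect_warning(rc <- incrementalR2(y, rep(1, n), X), "constant")
  expect_equal(rc$r2_increment, 0)
})

test_that("permuted null PRS gives calibrated increment p-values", {
  set.seed(92)
  n <- 150
  X <- cbind(age = rnorm(n, 50, 10), sexm = rbinom(n, 1, 0.5))
  y <- 120 + 0.4 * X[, 1] + rnorm(n, 0, 10)
  prs <- rnorm(n)
  ps <- vapply(1:200, function(i) {
    incrementalR2(y, sample(prs), X)$increment_p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("threshold selection maximizes the increment with parsimony ties", {
  expect_equal(selectBestThreshold(c("0.001" = 0.002, "0.05" = 0.006)), 0.05)
  expect_equal(selectBestThreshold(c("0.01" = 0.004)), 0.01)
  expect_equal(selectBestThreshold(c("0.0025" = 0.004, "0.05" = 0.004)),
               0.0025)
  expect_equal(selectBestThreshold(c("0.001" = NA, "0.025" = 0.001)), 0.025)
})

test_that("decile partition follows the rank rule", {
  set.seed(93)
  n <- 966
  prof <- data.frame(sample_id = sprintf("s%04d", 1:n), score = rnorm(n),
                     stringsAsFactors = FALSE)
  sbp <- rnorm(n, 150, 20)
  phen <- preparePhenotypes(data.frame(
    sample_id = prof$sample_id, sex = "female", age = 50,
    sbp = sbp, dbp = sbp - runif(n, 20, 60), on_med = FALSE,
    stringsAsFactors = FALSE))
  dt <- decileStratify(prof, phen, "SBP")
  expect_equal(sum(dt$n), n)
  expect_lte(diff(range(dt$n)), 1)
  expect_equal(dt$n, diff(c(0, ceiling(1:10 * n / 10))))

  # monotone construction: score-aligned trait gives non-decreasing means
  phen2 <- phen
  phen2$sbp <- 100 + 10 * rank(prof$score) / n
  phen2$dbp <- phen2$sbp - 40
  dt2 <- decileStratify(prof, preparePhenotypes(phen2[, 1:6]), "SBP")
  expect_true(all(diff(dt2$mean) >= 0))

  # degenerate equal scores: deterministic id-ordered partition
  prof3 <- prof; prof3$score <- 1
  dt3 <- decileStratify(prof3, phen, "SBP")
  expect_equal(sum(dt3$n), n)
  asg <- attr(dt3, "assignment")
  expect_identical(asg$decile, rep(1:10, times = dt3$n)[order(order(asg$sample_id))])
})

test_that("extreme-decile comparison matches the Welch oracle", {
  set.seed(94)
  x <- rnorm(97, 141.2, 33.5); y <- rnorm(97, 157.0, 31.7)
  cmp <- compareExtremeDeciles(x, y)
  orc <- welchOracle(x, y)
  expect_equal(cmp$t_stat, orc$t, tolerance = 1e-10)
  expect_equal(cmp$df, orc$df, tolerance = 1e-10)
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-10)
  expect_equal(cmp$cohens_d, abs(orc$t) * sqrt(2 / 97), tolerance = 1e-12)

  # equal group sizes: Welch statistic equals the pooled-variance statistic
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(cmp$t_stat, unname(pooled$statistic), tolerance = 1e-10)

  # identical groups and degenerate zero-variance input
  same <- compareExtremeDeciles(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  flat <- compareExtremeDeciles(rep(5, 10), rep(5, 12))
  expect_equal(flat$t_stat, 0); expect_equal(flat$p_value, 1)
  expect_equal(flat$cohens_d, 0)
})

test_that("Cohen's d conversion follows d = |t| sqrt(1/n1 + 1/n2)", {
  expect_equal(cohensDFromT(0, 50, 60), 0)
  expect_equal(cohensDFromT(-2, 100, 100), 2 * sqrt(0.02))
  expect_equal(cohensDFromT(3, 10, 40), 3 * sqrt(1 / 10 + 1 / 40))
  expect_error(cohensDFromT(1, 1, 10))
})

test_that("rank AUC matches the all-pairs oracle and is monotone-invariant", {
  # perfect separation
  expect_equal(aucRank(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # ties fixture
  sc <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 6, 7)
  lb <- c(0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1)
  expect_equal(aucRank(sc, lb), aucPairOracle(sc, lb), tolerance = 1e-12)
  # strictly monotone transform leaves AUC unchanged
  expect_equal(aucRank(exp(sc), lb), aucRank(sc, lb), tolerance = 1e-12)
  # null labels at n = 2000
  set.seed(95)
  s2 <- rnorm(2000); l2 <- rbinom(2000, 1, 0.4)
  expect_lt(abs(aucRank(s2, l2) - 0.5), 0.03)
  expect_error(aucRank(s2, rep(1, 2000)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(96)
  sc <- rnorm(300); lb <- rbinom(300, 1, plogis(sc))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucRank(sc, lb), ref, tolerance = 1e-10)
})

test_that("pathway PRS correlations form a valid matrix", {
  set.seed(97)
  a <- rnorm(500); b <- 0.7 * a + rnorm(500, 0, 0.5); cc <- rnorm(500)
  m <- cbind(p1 = a, p2 = b, p3 = cc, p4 = a)
  cm <- pathwayPrsCorrelation(m)
  expect_equal(diag(cm), c(p1 = 1, p2 = 1, p3 = 1, p4 = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["p1", "p4"], 1, tolerance = 1e-12)  # identical scores
  expect_lt(abs(cm["p1", "p3"]), 0.1)                 # independent pathways
  expect_gt(cm["p1", "p2"], 0.5)
  expect_warning(cmc <- pathwayPrsCorrelation(cbind(p1 = a,
                                                    p5 = rep(1, 500))),
                 "constant")
  expect_true(is.na(cmc["p1", "p5"]))
  expect_equal(cmc["p5", "p5"], 1)
})

test_that("disjoint null pathways give near-zero PRS correlation", {
  st <- simulateStudy(smallConfig(nDiscovery = 2000L, nValidation = 50L,
                                  nTarget = 50L, h2Prs = 0, nBlocks = 8L,
                                  genesPerBlock = 1L, nPathways = 4L,
                                  seed = 98))
  g <- st$discovery$genotypes
  v <- variantInfo(g)
  genes <- geneAnnotation(st$pool)
  pws <- pathwayDefinitions(st$pool)
  scores <- lapply(pws[c("pathway_01", "pathway_02")], function(gs) {
    ids <- mapSnpsToPathway(v, genes, gs)
    as.vector(dosages(g)[, ids] %*% withr::with_seed(1, runif(length(ids))))
  })
  cm <- pathwayPrsCorrelation(scores)
  expect_lt(abs(cm[1, 2]), 0.1)
})
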