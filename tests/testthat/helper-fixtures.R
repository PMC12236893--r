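# Shared fixtures and independent oracles used across the suite.

# A small, fast study configuration; override anything via ...
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nDiscovery = 300L, nValidation = 200L, nTarget = 200L,
                   nBlocks = 6L, snpsPerBlock = 5L, genesPerBlock = 2L,
                   nPathways = 3L, causalPathways = "pathway_01",
                   h2Prs = 0.15, seed = 42L)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

# Wrap a samples x variants dosage matrix into a GenotypeData with
# single-chromosome positions spaced `spacing` bp apart.
makeGenotypeData <- function(dos, chrom = "1", spacing = 1000L,
                             pos = NULL, maf = NULL) {
  nv <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%03d", seq_len(nrow(dos)))
  v <- data.frame(variant_id = sprintf("v%03d", seq_len(nv)),
                  chrom = rep(chrom, length.out = nv),
                  pos = if (is.null(pos)) seq_len(nv) * spacing else pos,
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!is.null(maf)) v$maf <- maf
  colnames(dos) <- v$variant_id
  GenotypeData(dos, v)
}

# Normal-equations OLS oracle: y on cbind(1, X); returns stats for X's
# first column (the dosage).
olsOracle <- function(y, X) {
  Xf <- cbind(1, as.matrix(X))
  XtXi <- solve(crossprod(Xf))
  b <- XtXi %*% crossprod(Xf, y)
  res <- y - Xf %*% b
  df <- length(y) - ncol(Xf)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  tv <- b / se
  list(beta = unname(b[2]), se = unname(se[2]),
       p = unname(2 * pt(-abs(tv[2]), df)))
}

# Exhaustive grid search over p_AB (margins fixed at the sample allele
# frequencies) maximizing the nine-class multinomial likelihood.
gridSearchPab <- function(d1, d2, step = 1e-4) {
  n <- length(d1)
  cnt <- tabulate(d1 * 3 + d2 + 1, nbins = 9)
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(pAB) {
    f <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
    if (any(f < 0)) return(-Inf)
    pr <- c(f[["ab"]]^2, 2 * f[["aB"]] * f[["ab"]], f[["aB"]]^2,
            2 * f[["Ab"]] * f[["ab"]],
            2 * (f[["AB"]] * f[["ab"]] + f[["Ab"]] * f[["aB"]]),
            2 * f[["AB"]] * f[["aB"]],
            f[["Ab"]]^2, 2 * f[["AB"]] * f[["Ab"]], f[["AB"]]^2)
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

# Textbook Welch statistic.
welchOracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# All-pairs AUC oracle (concordant + half ties).
aucPairOracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Independent greedy clumping over a precomputed full r2 matrix.
clumpOracle <- function(assoc, r2mat, windowBp, r2Max) {
  ord <- order(assoc$p_value, assoc$chrom, assoc$pos)
  active <- rep(TRUE, nrow(assoc))
  kept <- character(0)
  for (i in ord) {
    if (!active[i]) next
    active[i] <- FALSE
    kept <- c(kept, assoc$variant_id[i])
    drop <- active & assoc$chrom == assoc$chrom[i] &
      abs(assoc$pos - assoc$pos[i]) <= windowBp & r2mat[i, ] > r2Max
    active[drop] <- FALSE
  }
  kept
}
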