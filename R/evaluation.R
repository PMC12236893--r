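#' Incremental R-squared of a PRS over covariates
#'
#' Fits two OLS models on identical samples: trait ~ covariates (base) and
#' trait ~ covariates + PRS (full). The increment is their R-squared
#' difference (non-negative by nesting); \code{increment_p} is the
#' two-sided t-test p-value of the PRS coefficient in the full model. A
#' constant (or all-NA) PRS yields a zero increment with a warning.
#'
#' @param trait numeric trait vector (e.g. medication-adjusted mmHg).
#' @param prs numeric PRS vector, aligned with \code{trait}.
#' @param covariates numeric matrix/data.frame (age, sex, PCs), aligned.
#' @return list: r2_base, r2_full, r2_increment, increment_p, n.
#' @export
incrementalR2 <- function(trait, prs, covariates) {
  X <- as.matrix(covariates)
  keep <- stats::complete.cases(trait, prs, X)
  y <- trait[keep]; s <- prs[keep]; X <- X[keep, , drop = FALSE]
  if (length(y) < ncol(X) + 3L) stop("too few complete observations")
  r2 <- function(fit, y) 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  base <- stats::lm(y ~ X)
  r2b <- r2(base, y)
  if (length(unique(s)) < 2L) {
    warning("PRS is constant; incremental R2 is 0")
    return(list(r2_base = r2b, r2_full = r2b, r2_increment = 0,
                increment_p = NA_real_, n = length(y)))
  }
  full <- stats::lm(y ~ X + s)
  r2f <- r2(full, y)
  cf <- summary(full)$coefficients
  if (!"s" %in% rownames(cf) || is.na(stats::coef(full)[["s"]])) {
    # PRS aliased with the covariates: no additional variance explained
    warning("PRS is collinear with the covariates; incremental R2 is 0")
    return(list(r2_base = r2b, r2_full = r2b, r2_increment = 0,
                increment_p = NA_real_, n = length(y)))
  }
  pr <- cf["s", "Pr(>|t|)"]
  list(r2_base = r2b, r2_full = r2f, r2_increment = max(0, r2f - r2b),
       increment_p = pr, n = length(y))
}

#' Select the best-fit p-value threshold
#'
#' Argmax of the validation-cohort incremental R-squared over the threshold
#' grid; exact ties go to the smaller threshold (sparser model). NA
#' increments (e.g. empty models) count as zero.
#'
#' @param increments named numeric vector, names are thresholds.
#' @return the chosen threshold (numeric).
#' @export
selectBestThreshold <- function(increments) {
  stopifnot(length(increments) >= 1L)
  thr <- as.numeric(names(increments))
  inc <- ifelse(is.na(increments), 0, increments)
  o <- order(-inc, thr)
  thr[o[1]]
}

#' Decile stratification of a trait by PRS
#'
#' Samples are ranked by score (ties kept in sample-id order, so the
#' partition is deterministic); decile k holds ranks in
#' \code{(ceiling((k-1) n / 10), ceiling(k n / 10)]}, so group sizes differ
#' by at most one and sum to n. Per-decile n, mean and sample SD of the
#' trait are reported.
#'
#' @param profiles data.frame from [scoreSamples()] (sample_id, score).
#' @param phen prepared phenotype table.
#' @param trait one of "SBP", "DBP", "MAP", "PP".
#' @return data.frame decile, n, mean, sd, plus attribute
#'   \code{"assignment"} (data.frame sample_id, score, decile).
#' @export
decileStratify <- function(profiles, phen, trait = c("SBP", "DBP", "MAP", "PP")) {
  trait <- match.arg(trait)
  idx <- match(profiles$sample_id, phen$sample_id)
  if (anyNA(idx)) stop("phenotypes missing for scored samples")
  y <- .traitVector(phen[idx, , drop = FALSE], trait)
  keep <- !is.na(profiles$score)
  if (sum(keep) < 20L) stop("need at least 20 scored samples for deciles")
  sc <- profiles$score[keep]; ids <- profiles$sample_id[keep]; y <- y[keep]
  o <- order(sc, ids)
  n <- length(o)
  bounds <- ceiling(seq_len(10L) * n / 10)
  decile <- findInterval(seq_len(n) - 1L, bounds) + 1L  # rank r in (b[k-1], b[k]]
  assign <- integer(n)
  assign[o] <- decile
  tab <- do.call(rbind, lapply(1:10, function(k) {
    yk <- y[assign == k]
    data.frame(decile = k, n = length(yk), mean = mean(yk),
               sd = stats::sd(yk))
  }))
  attr(tab, "assignment") <- data.frame(sample_id = ids, score = sc,
                                        decile = assign,
                                        stringsAsFactors = FALSE)
  tab
}

#' Cohen's d from a two-sample t statistic
#'
#' \code{d = |t| sqrt(1/n1 + 1/n2)}, the conversion consistent with the
#' standardized mean difference for two groups of the given sizes.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes (>= 2).
#' @export
cohensDFromT <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  abs(t) * sqrt(1 / n1 + 1 / n2)
}

#' Compare extreme PRS deciles with a two-sample t-test
#'
#' Welch's t on the raw trait values of deciles 1 and 10 (with equal group
#' sizes the statistic coincides with the pooled-variance version), two-sided
#' p, and Cohen's d recovered from the statistic via [cohensDFromT()]. The
#' statistic is signed as decile 1 minus decile 10, so a risk-increasing
#' score gives a negative t. Two zero-variance groups with equal means give
#' t = 0, p = 1, d = 0.
#'
#' @param d1,d10 numeric trait values of the bottom and top decile.
#' @return one-row data.frame: n1, n10, mean1, sd1, mean10, sd10, t_stat,
#'   df, p_value, cohens_d.
#' @export
compareExtremeDeciles <- function(d1, d10) {
  d1 <- d1[!is.na(d1)]; d10 <- d10[!is.na(d10)]
  stopifnot(length(d1) >= 2L, length(d10) >= 2L)
  if (stats::sd(d1) == 0 && stats::sd(d10) == 0) {
    if (mean(d1) == mean(d10)) {
      tt <- list(statistic = 0, parameter = length(d1) + length(d10) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(d1) - mean(d10)) * Inf,
                 parameter = length(d1) + length(d10) - 2, p.value = 0)
    }
  } else {
    fit <- stats::t.test(d1, d10, var.equal = FALSE)
    tt <- list(statistic = unname(fit$statistic),
               parameter = unname(fit$parameter), p.value = fit$p.value)
  }
  data.frame(n1 = length(d1), n10 = length(d10),
             mean1 = mean(d1), sd1 = stats::sd(d1),
             mean10 = mean(d10), sd10 = stats::sd(d10),
             t_stat = tt$statistic, df = tt$parameter, p_value = tt$p.value,
             cohens_d = cohensDFromT(tt$statistic, length(d1), length(d10)))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability a random case outscores a random control, with ties counted
#' half: \code{AUC = (sum of case ranks - nPos (nPos + 1) / 2) /
#' (nPos nNeg)}. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric PRS values.
#' @param labels logical (or 0/1) case status; both classes must occur.
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Correlation structure of pathway-specific PRS
#'
#' Pearson correlations between per-pathway score vectors on the same
#' samples; constant score vectors produce NA off-diagonal entries (reported
#' with a warning), the diagonal is 1.
#'
#' @param scoresByPathway named list of numeric score vectors (same order of
#'   samples) or a samples x pathways matrix/data.frame.
#' @return symmetric correlation matrix.
#' @export
pathwayPrsCorrelation <- function(scoresByPathway) {
  m <- if (is.list(scoresByPathway) && !is.data.frame(scoresByPathway))
    do.call(cbind, scoresByPathway) else as.matrix(scoresByPathway)
  const <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                   all(is.na(x)))
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (any(const)) {
    warning("constant PRS vector(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations reported as NA")
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc) <- 1
  cc
}
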