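#' Ancestry principal components from a dosage matrix
#'
#' Mean-imputes missing dosages per variant, drops zero-variance variants
#' (with a warning), greedily LD-thins the panel (a variant is kept only if
#' its dosage r2 with every previously kept variant on the same chromosome
#' is below \code{thinR2}), then runs PCA on the column-standardized matrix.
#' Each component's sign is fixed by making its largest-magnitude variant
#' loading positive, so scores are reproducible.
#'
#' @param g a [GenotypeData].
#' @param k number of components, \code{k <= min(n_samples - 1, n_variants)}.
#' @param thinR2 LD-thinning r2 threshold (1 disables thinning).
#' @return n x k matrix of per-sample scores (columns PC1..PCk).
#' @export
computePCs <- function(g, k = 5, thinR2 = 0.2) {
  d <- dosages(g)
  v <- variantInfo(g)
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  vars <- apply(d, 2, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance variant(s) excluded from PCA")
    d <- d[, vars > 0, drop = FALSE]
    v <- v[vars > 0, , drop = FALSE]
  }
  if (thinR2 < 1) {
    keep <- logical(ncol(d))
    for (j in seq_len(ncol(d))) {
      prev <- which(keep & v$chrom == v$chrom[j])
      keep[j] <- !length(prev) ||
        all(stats::cor(d[, j], d[, prev, drop = FALSE])^2 < thinR2)
    }
    d <- d[, keep, drop = FALSE]
  }
  if (k > min(nrow(d) - 1L, ncol(d)))
    stop("k exceeds min(n_samples - 1, n_variants) after thinning")
  pc <- stats::prcomp(d, center = TRUE, scale. = TRUE, rank. = k)
  flip <- vapply(seq_len(k), function(i) {
    rot <- pc$rotation[, i]
    sign(rot[which.max(abs(rot))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosages(g))
  scores
}

# Oriented association result row: beta >= 0 with risk_allele set to the
# trait-increasing allele (alt when beta >= 0 pre-orientation, else ref).
.orient <- function(beta, se, p, ref, alt) {
  flipped <- beta < 0
  data.frame(beta = abs(beta), se = se, p_value = p,
             risk_allele = ifelse(flipped, ref, alt),
             other_allele = ifelse(flipped, alt, ref),
             flipped = flipped, stringsAsFactors = FALSE)
}

#' Per-SNP additive association fit
#'
#' Ordinary least squares of the trait on the dosage plus covariates and an
#' intercept; the two-sided p-value comes from the t distribution with
#' residual degrees of freedom. The result is oriented so the reported
#' effect is for the trait-increasing (risk) allele and is non-negative;
#' an exactly zero effect keeps the alt allele by convention.
#'
#' @param dosage numeric per-sample dosage vector (non-constant).
#' @param trait numeric trait vector (e.g. medication-adjusted mmHg).
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param ref,alt allele labels used for orientation.
#' @return one-row data.frame: beta, se, p_value, risk_allele, other_allele,
#'   flipped, n.
#' @export
fitSnpAssociation <- function(dosage, trait, covariates = NULL,
                              ref = "A", alt = "G") {
  if (stats::var(dosage, na.rm = TRUE) == 0)
    stop("monomorphic variant: dosage is constant")
  df <- data.frame(.y = trait, .d = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ranks <- qr(cbind(1, as.matrix(covariates)))$rank
    if (ranks < ncol(covariates) + 1L)
      stop("rank-deficient covariate design; collinear columns among: ",
           paste(colnames(covariates), collapse = ", "))
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients[".d", ]
  out <- .orient(cf[["Estimate"]], cf[["Std. Error"]], cf[["Pr(>|t|)"]],
                 ref, alt)
  out$n <- length(stats::residuals(fit))
  out
}

# Covariate matrix (age, sex, PCs) for a prepared phenotype table.
.covariateMatrix <- function(phen, pcs = NULL) {
  X <- cbind(age = phen$age, sex_male = as.numeric(phen$sex == "male"))
  if (!is.null(pcs)) X <- cbind(X, pcs)
  X
}

#' Genome scan: additive association for every polymorphic variant
#'
#' Aligns samples by id, builds the trait (medication-adjusted continuous
#' trait from [preparePhenotypes()]) and the covariate design (age, sex and
#' \code{nPcs} genotype principal components), then fits the per-variant
#' additive OLS model for all variants at once via QR residualization
#' (numerically identical to per-variant [fitSnpAssociation()]).
#' Monomorphic variants are skipped with a logged reason; missing dosages
#' are mean-imputed per variant.
#'
#' @param g a [GenotypeData] for the discovery cohort.
#' @param phen prepared phenotype table containing those samples.
#' @param trait one of "SBP", "DBP", "MAP", "PP".
#' @param nPcs number of ancestry PCs to include (0 for none).
#' @param pcs optional precomputed PC score matrix (overrides \code{nPcs}).
#' @return data.frame ordered by (chrom, pos): variant_id, chrom, pos,
#'   risk_allele, other_allele, beta, se, p_value, flipped, n; skipped
#'   variants are recorded in \code{attr(, "skipped")}.
#' @export
runGwas <- function(g, phen, trait = c("SBP", "DBP", "MAP", "PP"),
                    nPcs = 5, pcs = NULL) {
  trait <- match.arg(trait)
  d <- dosages(g)
  idx <- match(rownames(d), phen$sample_id)
  if (anyNA(idx))
    stop("phenotypes missing for sample(s): ",
         paste(utils::head(rownames(d)[is.na(idx)], 5), collapse = ", "))
  phen <- phen[idx, , drop = FALSE]
  y <- .traitVector(phen, trait)
  if (is.null(pcs) && nPcs > 0) pcs <- computePCs(g, k = nPcs)
  X <- cbind(1, .covariateMatrix(phen, pcs))

  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  v <- variantInfo(g)
  poly <- apply(d, 2, stats::var) > 0
  skipped <- data.frame(variant_id = v$variant_id[!poly],
                        reason = rep("monomorphic", sum(!poly)),
                        stringsAsFactors = FALSE)

  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  rd <- qr.resid(qrX, d[, poly, drop = FALSE])
  n <- nrow(d)
  dfRes <- n - ncol(X) - 1L
  ss <- colSums(rd^2)
  beta <- colSums(rd * ry) / ss
  rss <- sum(ry^2) - beta^2 * ss
  se <- sqrt(rss / dfRes / ss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), dfRes)

  vp <- v[poly, , drop = FALSE]
  out <- cbind(
    data.frame(variant_id = vp$variant_id, chrom = vp$chrom, pos = vp$pos,
               stringsAsFactors = FALSE),
    .orient(beta, se, p, vp$ref, vp$alt))
  out$n <- n
  out <- out[order(.chromOrder(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "trait") <- trait
  out
}

# Numeric-aware chromosome ordering ("1" < "2" < ... < "10" < "X").
.chromOrder <- function(chrom) {
  suppress <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(suppress), 1e6 + as.numeric(factor(chrom)), suppress)
}
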