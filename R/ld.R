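#' Clumping parameters
#'
#' Defaults: a 250 kb symmetric window around the index SNP and exclusion of
#' members with r2 strictly greater than 0.1 (r2 exactly 0.1 is retained).
#'
#' @param windowBp window half-width in base pairs (> 0).
#' @param r2Max LD r2 exclusion threshold in (0, 1].
#' @export
clumpParams <- function(windowBp = 250000, r2Max = 0.1) {
  stopifnot(windowBp > 0, r2Max > 0, r2Max <= 1)
  list(windowBp = windowBp, r2Max = r2Max)
}

#' Maximum-likelihood two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; capital =
#' alt allele) from unphased integer dosages at two loci. All nine two-locus
#' genotype classes determine their haplotypes except the double
#' heterozygote, whose coupling/repulsion split is the only latent quantity;
#' the EM iteration starts at linkage equilibrium and runs until the largest
#' frequency change drops below \code{tol} (or \code{maxIter}). The
#' multinomial log-likelihood is non-decreasing across iterations (returned
#' as a trace). Fractional dosages must be rounded by the caller.
#'
#' @param d1,d2 integer dosage vectors (0/1/2, NA allowed pairwise-removed),
#'   same samples; both loci must be polymorphic.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param maxIter iteration cap.
#' @return list: \code{freq} (named pAB/pAb/paB/pab), \code{D}, \code{r2},
#'   \code{loglik}, \code{iterations}, \code{llTrace}.
#' @export
estimateHaplotypeFreqs <- function(d1, d2, tol = 1e-10, maxIter = 1000) {
  keep <- !(is.na(d1) | is.na(d2))
  d1 <- d1[keep]; d2 <- d2[keep]
  if (!all(d1 %in% 0:2) || !all(d2 %in% 0:2))
    stop("EM requires integer dosages in {0,1,2}; round fractional dosages first")
  n <- length(d1)
  cnt <- tabulate(d1 * 3 + d2 + 1, nbins = 9)  # index = g1*3 + g2, row-major
  nn <- function(g1, g2) cnt[g1 * 3 + g2 + 1]
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic locus: r2 undefined")

  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  ll <- function(f) {
    pr <- c(f["ab"]^2, 2 * f["aB"] * f["ab"], f["aB"]^2,          # g1 = 0
            2 * f["Ab"] * f["ab"], 2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"]),
            2 * f["AB"] * f["aB"],                                 # g1 = 1
            f["Ab"]^2, 2 * f["AB"] * f["Ab"], f["AB"]^2)           # g1 = 2
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }
  llTrace <- ll(f)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- f[["AB"]] * f[["ab"]] + f[["Ab"]] * f[["aB"]]
    cc <- if (denom > 0) f[["AB"]] * f[["ab"]] / denom else 0.5
    nDH <- nn(1, 1)
    cAB <- 2 * nn(2, 2) + nn(2, 1) + nn(1, 2) + cc * nDH
    cAb <- 2 * nn(2, 0) + nn(2, 1) + nn(1, 0) + (1 - cc) * nDH
    caB <- 2 * nn(0, 2) + nn(1, 2) + nn(0, 1) + (1 - cc) * nDH
    cab <- 2 * nn(0, 0) + nn(1, 0) + nn(0, 1) + cc * nDH
    fNew <- c(AB = cAB, Ab = cAb, aB = caB, ab = cab) / (2 * n)
    delta <- max(abs(fNew - f))
    f <- fNew
    llTrace <- c(llTrace, ll(f))
    if (delta < tol || it >= maxIter) break
  }
  D <- f[["AB"]] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(freq = f, D = D, r2 = min(1, r2), loglik = llTrace[length(llTrace)],
       iterations = it, llTrace = unname(llTrace))
}

#' Pairwise LD r2 between two dosage vectors
#'
#' Default estimator is the EM maximum-likelihood haplotype-frequency r2 on
#' rounded dosages; \code{method = "dosage"} gives the squared Pearson
#' correlation of the (possibly fractional) dosages instead.
#'
#' @param d1,d2 dosage vectors on the same samples.
#' @param method "em" or "dosage".
#' @export
ldR2 <- function(d1, d2, method = c("em", "dosage")) {
  method <- match.arg(method)
  if (method == "dosage") {
    keep <- !(is.na(d1) | is.na(d2))
    return(stats::cor(d1[keep], d2[keep])^2)
  }
  estimateHaplotypeFreqs(round(d1), round(d2))$r2
}

#' Greedy p-value-ordered LD clumping
#'
#' Repeats until all variants are processed: the unprocessed variant with
#' the smallest association p-value becomes an index (ties broken by
#' chromosome, then position); every remaining variant on the same
#' chromosome within \code{windowBp} of the index whose r2 with it exceeds
#' \code{r2Max} (strictly) is removed as a member of that clump. Retained
#' and removed variants partition the input.
#'
#' @param assoc association data.frame (variant_id, chrom, pos, p_value) as
#'   from [runGwas()]; all its variants must be present in \code{g}.
#' @param g the [GenotypeData] whose samples supply the LD estimates.
#' @param params a [clumpParams()] list.
#' @param method LD estimator passed to [ldR2()]; EM works on rounded
#'   dosages (a member whose rounded dosage is constant falls back to the
#'   dosage estimator).
#' @return list: \code{index} (retained variant ids, by ascending p),
#'   \code{members} (named list index -> removed ids), \code{log}
#'   (data.frame member, index, r2, distance), \code{params}.
#' @export
greedyClump <- function(assoc, g, params = clumpParams(),
                        method = c("em", "dosage")) {
  method <- match.arg(method)
  if (nrow(assoc) == 0L)
    return(list(index = character(0), members = list(),
                log = data.frame(member = character(0), index = character(0),
                                 r2 = numeric(0), distance = numeric(0)),
                params = params))
  d <- dosages(g)
  missing <- setdiff(assoc$variant_id, colnames(d))
  if (length(missing))
    stop("association variants absent from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  d <- d[, assoc$variant_id, drop = FALSE]
  if (method == "em") d <- round(d)

  ord <- order(assoc$p_value, .chromOrder(assoc$chrom), assoc$pos)
  active <- rep(TRUE, nrow(assoc))
  index <- character(0)
  members <- list()
  logRows <- list()
  for (i in ord) {
    if (!active[i]) next
    active[i] <- FALSE
    id <- assoc$variant_id[i]
    index <- c(index, id)
    cand <- which(active & assoc$chrom == assoc$chrom[i] &
                  abs(assoc$pos - assoc$pos[i]) <= params$windowBp)
    removed <- character(0)
    for (j in cand) {
      r2 <- if (method == "em") {
        if (stats::var(d[, j]) == 0 || stats::var(d[, i]) == 0)
          ldR2(dosages(g)[, assoc$variant_id[i]],
               dosages(g)[, assoc$variant_id[j]], method = "dosage")
        else estimateHaplotypeFreqs(d[, i], d[, j])$r2
      } else ldR2(d[, i], d[, j], method = "dosage")
      if (r2 > params$r2Max) {
        active[j] <- FALSE
        removed <- c(removed, assoc$variant_id[j])
        logRows[[length(logRows) + 1L]] <- data.frame(
          member = assoc$variant_id[j], index = id, r2 = r2,
          distance = abs(assoc$pos[j] - assoc$pos[i]),
          stringsAsFactors = FALSE)
      }
    }
    members[[id]] <- removed
  }
  list(index = index, members = members,
       log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(member = character(0), index = character(0),
                    r2 = numeric(0), distance = numeric(0)),
       params = params)
}

#' Write a clump report TSV
#'
#' One row per index SNP: id, chrom, pos, p, number of clumped members and
#' the member id list.
#'
#' @param clump result of [greedyClump()].
#' @param assoc the association table used for clumping.
#' @param path output path.
#' @export
writeClumpReport <- function(clump, assoc, path) {
  idx <- match(clump$index, assoc$variant_id)
  out <- data.frame(
    index_id = clump$index,
    chrom = assoc$chrom[idx], pos = assoc$pos[idx],
    p_value = assoc$p_value[idx],
    n_members = lengths(clump$members[clump$index]),
    members = vapply(clump$members[clump$index], function(m)
      if (length(m)) paste(m, collapse = ",") else ".", character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
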