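# pathwayPRS

Pathway-specific polygenic risk scores (PRS) for blood-pressure traits by
clumping and thresholding, evaluated across a discovery / validation /
target cohort design.

## What problem this solves

Genome-wide PRS stratify hypertension risk but give no insight into how
that risk is distributed over biological pathways. Restricting a PRS to the
genes of pathways targeted by first-line anti-hypertensive drugs
(beta-blockers, calcium channel blockers, ACE inhibitors, angiotensin
receptor blockers) makes the score biologically interpretable.
`pathwayPRS` is a complete, tested R implementation of that workflow for
four blood-pressure traits — SBP, DBP, mean arterial pressure
(MAP = (SBP + 2·DBP)/3) and pulse pressure (PP = SBP − DBP) — for
statistical geneticists who want a reproducible, oracle-checked C+T
pipeline at cohort scale.

The core method, per trait and pathway gene set:

1. **Discovery GWAS.** For each SNP *j*, OLS of the medication-adjusted
   trait (+15/+10 mmHg added to SBP/DBP of treated samples) on the
   risk-allele dosage with age, sex and 5 ancestry PCs as covariates:
   *y* = α + β·d + γ'c + ε. Effects are oriented so β ≥ 0 for the
   trait-increasing allele.
2. **LD clumping.** Greedy, in p-value order: SNPs within 250 kb of an
   index SNP with r² > 0.1 are removed. r² comes from maximum-likelihood
   two-locus haplotype frequencies estimated by EM from unphased dosages.
3. **Thresholding.** Candidate models keep clump-retained SNPs with
   p ≤ t for t in {0.001, 0.0025, 0.005, 0.0075, 0.01, 0.025, 0.05};
   scores are the weighted mean risk-allele dosage per allele,
   PRS_i = Σ w_j d_ij / (2 m_i).
4. **Validation.** The threshold maximizing the incremental R²
   (R²_full − R²_base over the covariate-only model) is selected.
5. **Target evaluation.** Incremental R², PRS deciles, Welch t-test
   between deciles 1 and 10 with Cohen's d = |t|·√(1/n₁ + 1/n₁₀), and
   rank-based AUC for hypertension (SBP ≥ 140 / DBP ≥ 90 / on medication).

Because cohort genotypes of this kind cannot be redistributed, the package
includes a synthetic-study generator (`simulateStudy()`) with LD-block
genotypes in closed form, pathway-annotated genes and a known additive
phenotype model, so the whole pipeline is testable end to end.

## Worked example

```r
library(pathwayPRS)

cfg <- simulationConfig(nDiscovery = 300, nValidation = 200, nTarget = 200,
                        nBlocks = 6, snpsPerBlock = 5, genesPerBlock = 2,
                        nPathways = 3, h2Prs = 0.15, seed = 42)
study <- simulateStudy(cfg)           # 3 cohorts, causal pathway_01
res <- runStudyPipeline(study, traits = "SBP")
res$summary[, c("pathway_id", "chosen_threshold", "n_snps",
                "r2_increment", "increment_p", "auc")]
#>                pathway_id chosen_threshold n_snps r2_increment increment_p
#> SBP.pathway_01 pathway_01            0.050      2        0.126    9.09e-08
#> SBP.pathway_02 pathway_02            0.001      0        0.000          NA
#> SBP.pathway_03 pathway_03            0.001      0        0.000          NA
#> SBP.combined     combined            0.050      2        0.126    9.09e-08
#>                  auc
#> SBP.pathway_01 0.703
#> SBP.pathway_02    NA
#> SBP.pathway_03    NA
#> SBP.combined   0.703

res$reports$SBP.combined
#> EvaluationReport: SBP / combined (threshold 0.05, 2 SNPs)
#>   R2 base 0.0939 -> full 0.2201 (increment 0.1261, p = 9.09e-08)
#>   deciles 1 vs 10: t = -3.539, p = 0.00116, Cohen's d = 1.12
#>   hypertension AUC = 0.703
```

Reading: the simulated causal pathway (`pathway_01`) carries all the
signal — adding its PRS to the covariate-only model lifts R² by 0.126 on
the held-out target cohort, the top PRS decile has markedly higher SBP
than the bottom decile (t = −3.54), and the score separates hypertensive
from normotensive samples with AUC 0.70. The two null pathways select
empty models (no SNP survives any threshold) and contribute nothing, as
they should. At the default full-scale configuration (cohorts
2295/1614/966, 22 blocks × 10 SNPs, 11 pathways) the same structure holds
with tighter estimates.

Real data enter through `readGenotypes()` (VCF with DS/GT, or dosage-TSV),
`readPhenotypeTsv()`, and `readGeneSets()` (GMT + BED, GRCh37-style
1-based internal coordinates), followed by `applyVariantQC()` (MAF < 0.05,
info < 0.3, missingness > 5%, exact Hardy–Weinberg p < 1e-6) and
`runPipeline()`.

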