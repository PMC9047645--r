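# pqtlmeta

Post-cohort statistics for protein quantitative trait locus (pQTL)
genome-wide association studies, for analysts who receive per-cohort GWAS
summary statistics of a circulating protein and need to take them all the
way to biology: combined discovery, secondary signals, variance
accounting, causal inference on a disease outcome, and annotation
enrichment.

The package covers, as composable R functions:

* **Fixed-effect inverse-variance meta-analysis** across cohorts
  (`ivw_meta()`), with sex-stratified X-chromosome records combined under
  0/1 male dosage coding (`x_chrom_meta()`), Cochran's Q, and a MAF filter
  on the meta allele frequency;
* **Exact meta-subtraction** (`meta_subtract()`): removing one cohort's
  contribution algebraically, `w_rem = w_meta − w_cohort`, to build
  overlap-free replication datasets;
* **LD tools** from a reference panel: `ld_pair()` (r², D′ by haplotype
  counting or two-locus EM), bias-adjusted `ld_scores()`, greedy p-value
  `clump()`ing and distance-based `define_loci()`;
* **Conditional & joint multi-SNP analysis** (`joint_fit()`,
  `conditional_scan()`): `b_J = R⁻¹ b_m` on the standardized scale with
  forward selection for secondary signals;
* **Variance explained** per lead variant, `2f(1−f)β²`, and the fraction
  of an externally estimated heritability (`variance_explained()`);
* **Two-sample Mendelian randomization** (`select_instruments()`,
  `wald_ratio()`, `ivw_mr()`, `bidirectional_mr()`): cis instruments
  clumped at r² < 0.001 inside a gene window, genome-wide instruments at
  r² < 0.05, Wald ratios combined by fixed-effect IVW and reported as an
  odds ratio with 95% CI;
* **LD-corrected annotation enrichment** (`annotate_snps()`,
  `fit_enrichment()`, `enrichment_scan()`): a per-SNP logistic regression
  `logit Pr(P_j < 5e-8) = μ + δ·ℓ_j + β·C_j`, where `ℓ_j` is the LD score
  and `C_j` annotation membership, with Firth fallback under separation
  and BH FDR across tracks;
* **A synthetic multi-cohort study generator** (`sim_config()`,
  `simulate_study()`) with full ground truth — block-LD Gaussian-copula
  haplotypes, a strong X cis locus plus trans loci on a polygenic
  background (h² = 0.16), a binary outcome causally downstream of the
  protein, and enriched annotation tracks — so every stage is validated
  against known parameters.

Inputs are GWAS-SSF style tab-separated summary statistics
(`read_sumstats()` handles foreign column dialects), VCF reference panels
(`read_ld_vcf()`), and BED annotation tracks. A thin command-line front
end over the same functions is installed at `inst/cli/pqtlmeta`.

## Worked example

Simulate the default study (3 cohorts × 5000 individuals, 1200 autosomal
+ 240 X variants, a 3-signal cis locus and six trans effects, causal
effect θ = 0.4 of the protein on a binary outcome) and run the full
pipeline:

```r
library(pqtlmeta)
cfg   <- sim_config(seed = 1)
study <- simulate_study(cfg)
report <- run_pipeline(pipeline_config(sim = cfg), study = study)
report
#> Pipeline report
#>   lambda: 4.165
#>   loci: 11  secondary signals: 1
#>   cis MR OR: 1.594 [1.041-2.441] P=0.032
#>   enrichment beta: 1.566 (P=0.00157)
```

Reading the output: the genomic-control lambda is far above 1 because at
desk scale the full h² = 0.16 is spread over ~1400 variants, so the
polygenic background is individually visible (under a null configuration
lambda is ≈ 1). Eleven distance-merged loci pass 5×10⁻⁸ — the nine
planted causal variants (eight recovered genome-wide significant this
seed, all nine estimated within 3 SE of truth) plus discoverable
polygenic background; the conditional scan finds the one planted
secondary signal. The cis MR odds ratio 1.59 (95% CI 1.04–2.44)
recovers the simulated causal effect (true OR = e^0.4 ≈ 1.49), the
replication estimate after subtracting one cohort agrees, and reverse MR
instrumenting on the outcome's own risk loci is null (P = 0.28), the
expected signature of a protein → disease causal direction. The
enrichment log odds ratio 1.57 (P = 0.002) detects the planted 5-fold
annotation enrichment of causal variants.

Individual stages are plain functions, e.g.:

```r
meta <- ivw_meta(study$cohorts)                         # all strata
xcmb <- x_chrom_meta(meta[meta$stratum == "male", ],
                     meta[meta$stratum == "female", ])
inst <- select_instruments(xcmb, study$outcome, study$panel,
                           mode = "cis", cis_window = study$truth$cis_window)
ivw_mr(inst)
```

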