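---
title: "Methods: post-cohort statistics for protein QTL GWAS"
author: "pqtlmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-cohort statistics for protein QTL GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`pqtlmeta` implements the statistical stages that sit between per-cohort
GWAS summary statistics for a circulating protein and the downstream
biology: meta-analysis, secondary-signal discovery, variance accounting,
causal inference by Mendelian randomization (MR), and annotation
enrichment. The motivating use case is a plasma-protein (pQTL) study in
which a strong X-chromosome cis locus coexists with several autosomal
trans loci, the phenotype is rank-inverse-normal transformed per cohort,
and the X chromosome is analysed separately in males (0/1 dosage coding)
and females (0/1/2).

Every method operates on summary statistics plus a genotype LD reference
panel; no individual-level data crosses a module boundary except inside
the synthetic-data generator.

## Inverse-variance meta-analysis

Cohort estimates are combined with fixed-effect inverse-variance weights
(the standard-error scheme): with $w_i = 1/\mathrm{SE}_i^2$,

$$\hat\beta_\text{meta} = \frac{\sum_i w_i \hat\beta_i}{\sum_i w_i},
\qquad \mathrm{SE}_\text{meta} = \Big(\sum_i w_i\Big)^{-1/2}.$$

Cochran's $Q$ is reported per variant but never switches the model to
random effects: the estimator is deliberately fixed-effect throughout, and
the generator simulates a fixed-effect world (no between-cohort effect
heterogeneity) to match. Variants observed in a subset of cohorts pass
through with `k_cohorts` recorded; a minor-allele-frequency filter
(default MAF > 0.01) applies to the sample-size-weighted meta EAF.

Male and female X-chromosome strata are meta-analysed like two cohorts.
Under 0/1 male coding the per-allele effect is the same in both sexes when
the biology is dosage-compensated, which is what the generator simulates
and the tests verify.

`meta_subtract()` removes one cohort algebraically
($w_\text{rem} = w_\text{meta} - w_c$, etc.), the exact inverse of adding
it. This builds overlap-free replication datasets when an outcome GWAS
shares a contributing cohort with the exposure meta-analysis. No
genomic-control scaling is applied during subtraction: the inputs here are
simulated without confounding, and applying an arbitrary correction would
break the exact-inverse property that the tests assert.

## Variance explained and heritability fraction

Under Hardy-Weinberg equilibrium a biallelic additive variant with allele
frequency $f$ and per-allele effect $\hat\beta$ on a unit-variance
phenotype explains $2f(1-f)\hat\beta^2$ of the phenotypic variance. The
report always prints the captured variance $V$, the externally supplied
heritability $h^2$, and their ratio, rather than a single rounded
fraction — the ratio is only as meaningful as its denominator, which in
real studies comes from a separate whole-genome estimator and may or may
not include the X contribution.

## LD statistics, clumping and locus definition

$r^2$ is the squared Pearson correlation of reference-panel dosages. $D'$
uses haplotype counting when the panel is phased and a two-locus EM
haplotype-frequency estimate otherwise. LD scores are
$\ell_j = 1 + \sum_k \tilde r^2_{jk}$ over the window (default 1 Mb as a
proxy for 1 cM), with the standard finite-sample adjustment
$\tilde r^2 = r^2 - (1-r^2)/(n_\text{ref}-2)$.

Clumping is the classic greedy reduction: take the most significant
remaining variant as index, absorb everything within the window above the
$r^2$ threshold, repeat. Ties in $p$ break by position then allele so the
result is order-invariant; the implementation is tested for exact
equality against a brute-force oracle. The defaults follow the thresholds
conventionally used for instrument selection: $r^2 < 0.001$ within a cis
region (window 10 Mb, generous because a cis signal can sit ~100 kb from
the gene) and $r^2 < 0.05$ genome-wide (window 1 Mb).

Counting "independent loci" in the pipeline report is a different task
from instrument selection, and uses distance-based merging (one lead per
1 Mb window, `define_loci()`). With an $r^2$ rule, partially linked
variants at the edge of a true locus survive as spurious extra "loci";
distance merging matches how GWAS reports count loci.

## Conditional and joint analysis

`joint_fit()` re-estimates mutually adjusted effects from marginal
statistics and a reference LD correlation matrix $R$: on the standardized
scale $b_J = R^{-1} b_m$ with
$\mathrm{Var}(b_J) = \sigma^2_J \,\mathrm{diag}(R^{-1})/n$ and
$\sigma^2_J = 1 - b_J^\top b_m$. Numerical choices: a ridge of $10^{-6}$
on $R$'s diagonal; $\sigma^2_J$ floored at $10^{-6}$ (panel/sample LD
mismatch can otherwise drive it negative); a condition-number cap that
rejects near-singular sets with advice to pre-prune at $r^2 < 0.9$. The
sample size is taken from the meta `n`; per-variant effective-n
heterogeneity adjustment is out of scope.

`conditional_scan()` does forward selection from the locus lead, admitting
at each step the candidate with the smallest conditional $p$ below
`p_enter` (default $5\times10^{-8}$). Candidates with $r^2 > 0.9$ to the
current selection are skipped. The scan records each admitted variant's
marginal and conditional $p$, because the interesting phenomenon — a
variant whose conditional $p$ is smaller than its marginal $p$ — arises
under masking (e.g. negative LD between two positive effects) and is
validated in simulation rather than matched to any particular dataset.

## Two-sample Mendelian randomization

Instruments are genome-wide significant exposure variants
($P < 5\times10^{-8}$), clumped at the mode-specific $r^2$, joined to the
outcome by position and harmonized to the exposure's allele orientation.
The per-instrument Wald ratio is $\hat\beta_y/\hat\beta_x$ with
first-order SE $|\mathrm{SE}_y/\hat\beta_x|$; the fixed-effect IVW
combination

$$\hat\theta = \frac{\sum_i \beta_{x,i}\beta_{y,i}/\mathrm{SE}_{y,i}^2}
{\sum_i \beta_{x,i}^2/\mathrm{SE}_{y,i}^2}$$

is algebraically the inverse-variance-weighted mean of the Wald ratios
(asserted numerically in the tests). With a binary outcome the estimate
exponentiates to an odds ratio with a 95% Wald CI. A multiplicative
random-effects option inflates the SE by $\max(1, \sqrt{Q/(k-1)})$ behind
a flag; the fixed-effect form is primary. Pleiotropy-robust estimators
(Egger, weighted median) and outlier filtering are deliberately out of
scope: the cis design is the pleiotropy defence, and the genome-wide
analysis is plain multi-instrument IVW.

A caveat the vignette should not hide: with a logistic outcome model the
per-SNP log-odds effects are attenuated by non-collapsibility, so the IVW
estimate recovers roughly $0.97\,\theta$ at $\theta = 0.4$ — well inside
the simulation confidence intervals, but a real bias at much larger
effects.

## Allele harmonisation

Records are aligned by allele identity, then by strand complement;
palindromic (A/T, C/G) variants are resolved by comparing allele
frequencies only when both sides have MAF below 0.42, and are otherwise
excluded. These rules are a design choice of this package (methods
sections rarely state them); they are conservative, and the
harmonisation is involution-consistent (aligning back recovers the
original record, tested property-style).

## Annotation enrichment

The enrichment model regresses the indicator of genome-wide significance
on the variant's LD score and its annotation membership:

$$\log\frac{\Pr(P_j < 5\times10^{-8})}{\Pr(P_j \ge 5\times10^{-8})}
 = \mu + \delta\,\ell_j + \beta\,C_j ,$$

so $\beta$ is the log odds ratio of significant associations inside the
annotation, corrected for LD via $\ell_j$ as a covariate (no LD pruning
beforehand). Fitting is maximum likelihood by IRLS (`glm`), tolerance
$10^{-8}$, 100 iterations; with one annotated/significance cell empty the
likelihood separates and a Firth-penalized fit (Jeffreys prior) is
substituted with a warning. BED input is 0-based half-open and converted
at the boundary: a variant at 1-based position $p$ is annotated iff
$p-1$ lies in an interval. Multiple tracks are scanned with
Benjamini-Hochberg FDR across tracks (5% is the convention adopted here;
with one track $q = p$). An optional mask for the extended MHC region
(chr6:25-34 Mb) is available for real-data use and off by default, which
suits simulated maps.

# The synthetic study generator

The generator is first-class, tested code; it defines the statistical
world every guarantee is validated in.

**Genotypes.** Haplotypes follow a Gaussian copula: within an LD block a
latent AR(1) process with parameter $\rho$ is thresholded at
$\Phi^{-1}(1-f_j)$, so carrier probability is exactly $f_j$ and the
two-locus haplotype probabilities have a closed form (the adjacent-pair
orthant probability is used as the oracle in tests). Blocks are mutually
independent; genotypes are sums of two haplotypes; hemizygous males carry
one X haplotype, coded 0/1. This was chosen over coalescent simulation
because LD is controllable in closed form and no external tool is needed.

**Phenotype.** $y = \sum_j b_j g_j + \varepsilon$ with declared cis and
trans effects specified on the standardized scale (one variant's variance
contribution is $\beta^2 = 2f(1-f)b^2$), a polygenic background of tiny
random-sign effects on all autosomal variants outside the declared (and
outcome-direct) blocks filling the target heritability
($h^2 = 0.16$ by default), and noise scaled to unit total variance. The
phenotype is rank-inverse-normal transformed per cohort (Blom offset
3/8) before the per-variant OLS regressions, mirroring standard practice
for protein abundances. Cohort covariates (age, principal components) are
omitted: they are nuisance to the downstream summary-statistic math under
test.

**Default study conditions** (chosen once): 3 cohorts of 5000, 1200
autosomal + 240 X variants in blocks of 20 with $\rho = 0.8$, MAF drawn
from (0.05, 0.5); a cis X architecture of three independent signals
(standardized effects 0.11, 0.06, 0.06, together ~1.9% of variance);
five trans loci of effect 0.08 plus a weaker secondary signal (0.06)
three variants away inside the last trans locus, so the conditional scan
has a genuine discovery to make; $h^2 = 0.16$.

**Outcome.** A separate sample (default 20 000) with case status
$\sim\text{Bernoulli}(\text{logit}^{-1}(\alpha + \theta y + \gamma^\top
g_\text{direct}))$; $\alpha$ is solved numerically for the target
prevalence (0.1). $\theta = 0.4$ on the log-odds scale per SD of protein.
The direct loci ($\gamma = 0.3$ at two autosomal variants outside all
protein loci) give the outcome genome-wide significant associations of
its own; a reverse MR instruments on exactly these, and because they
carry no protein effect the reverse estimate is null — the structure a
bidirectional analysis is meant to detect. Per-variant outcome statistics
come from logistic regressions (vectorised Newton-Raphson); X variants
are fitted per sex and combined by IVW.

**Annotations.** Membership is drawn per variant with
$\Pr(\text{annotated}\mid\text{causal})$ set so causal variants are
enriched at the configured odds ratio (default 5) over the base rate
(0.1), then materialised as single-position BED intervals.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: population stratification and other
confounding, relatedness, imputation uncertainty, between-cohort effect
heterogeneity, INDELs/multiallelics, palindromic strand ambiguity (allele
pairs are drawn non-palindromic; the harmonisation rules are exercised by
unit tests instead), and realistic marker density. The last point matters
for interpretation: with $h^2 = 0.16$ spread over ~1400 variants instead
of millions, every variant carries a genuinely non-null polygenic effect,
so the genomic-control lambda of the default study is far above 1 and a
handful of background loci legitimately reach genome-wide significance.
That is polygenicity, not miscalibration — under a null configuration
($h^2 = 0$) lambda sits in [0.95, 1.05].

# Problem sizes used in the tests

The validation suite runs at desk scale, chosen to keep each property
demonstrable with comfortable statistical margins: the meta-vs-pooled-OLS
oracle uses 6000 individuals in 3 cohorts over 2000 variants; parameter
recovery 100 seeds at $n = 10\,000$; the conditional oracle 100 seeds per
LD regime ($r \in \{-0.5, 0, 0.5\}$) at $n = 8000$; MR coverage 100 seeds
($n_\text{outcome} = 20\,000$), type-I error 500 seeds, directionality
100 seeds ($n_\text{outcome} = 40\,000$); enrichment calibration 500
seeds with power checks at $n = 20\,000$ over 500 independent variants
(LD set to zero there so the 20 planted causal variants are the
significant set and the annotation contrast is undiluted); clumping
equivalence 50 seeds on 200-variant panels.

# Known limitations

* The conditional scan reports trajectories but does not attempt to
  reproduce any specific dataset's conditioning set.
* First-order Wald SEs ignore exposure uncertainty; fine for strong
  instruments (the selection threshold guarantees them), anticonservative
  for weak ones.
* LD scores use a single window parameter rather than genetic-map
  distance.
* `meta_subtract` assumes the subtracted cohort's statistics are exactly
  those that entered the meta-analysis (no intermediate rounding).
* The enrichment scan treats tracks as independent tests; overlapping
  chromatin states in real data are positively dependent, where BH
  remains valid but conservative.
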