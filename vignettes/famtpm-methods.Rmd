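---
title: "Methods: family-based tests with truncated-product gene and gene-family combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based tests with truncated-product gene and gene-family combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem famtpm addresses

Candidate-gene studies of complex quantitative traits routinely find that no
single variant survives correction for multiple testing, even when a gene or
a family of functionally related genes is genuinely associated: each common
variant carries a small effect, and the evidence is spread across many
correlated SNPs. famtpm implements the joint-association strategy for
family-based designs: test each SNP with a transmission-based score that is
robust to population stratification, then pool the single-SNP p-values into
gene-level and gene-family-level statistics whose null distribution respects
the linkage disequilibrium (LD) among the SNPs.

The motivating design is a multi-centre study of multiplex pedigrees --
roughly 94 extended families totalling about 3,665 members -- genotyped at
61 tagSNPs in the seven nicotinic acetylcholine receptor genes
(CHRNA3--CHRNA6, CHRNB2--CHRNB4), with four obesity phenotypes: body-mass
index (BMI, kg/m^2), waist circumference (WC, cm), waist-to-hip ratio (WHR)
and percent body fat (%BF). Because individual-level data of such studies
are restricted, the package ships a synthetic-data generator that emulates
the design with known ground truth; every distributional claim below is
exercised against it in the test suite.

## Single-SNP family-based test

For trait $y$ the package first forms residuals
$T_j = \log y_j - x_j^\top\hat\beta$ by ordinary least squares of the
log-transformed trait on the covariate design (age, sex, study centre,
ever-smoking, alcohol, physical activity, energy intake, socioeconomic
score, diabetes by default; categorical covariates expand to indicators).
The log transform tames the right skew of anthropometric traits; the offset
subtracted is the fitted mean, so residuals sum to zero.

Each nuclear family (extended pedigrees are decomposed into their nuclear
units, treated as independent contributions) contributes a score that
conditions on the parental genotypes $g_f, g_m \in \{0,1,2\}$ (minor-allele
counts). Given both parents, an offspring's genotype $X$ has the exact
Mendelian distribution with
$E[X] = (g_f+g_m)/2$ and
$\mathrm{Var}(X) = \tfrac{g_f}{2}(1-\tfrac{g_f}{2}) +
\tfrac{g_m}{2}(1-\tfrac{g_m}{2})$.
The SNP-level statistic aggregates over phenotyped offspring $j$:

$$U = \sum_j T_j\,(X_j - E[X_j \mid \text{parents}]), \qquad
  V = \sum_j T_j^2\,\mathrm{Var}(X_j \mid \text{parents}), \qquad
  Z = U/\sqrt{V},$$

with a two-sided p-value from the normal approximation. Only transmissions
are random under the null, which is what makes the test immune to
population structure and admixture. A family whose parents cannot segregate
(conditional variance zero) is uninformative; SNPs with fewer than
`min_informative = 10` informative families report a missing p-value. The
ratio $b = U/V$ is exported as an effect-size proxy.

Families with a missing parental genotype are skipped rather than handled
by a sufficient-statistic construction; the generator produces complete
parents, and the module boundary leaves room to add partial-parent handling
later. Coding is additive only.

## Gene and gene-family combination: weighted truncated product

The gene-level statistic over the p-values $p_i$ of the SNPs in a gene is
the (weighted) truncated product

$$W = \prod_i p_i^{\,w_i\,I(p_i \le \tau)},$$

the product of the p-values at or below the truncation threshold $\tau$
(default 0.05, the canonical choice), each raised to its weight. All
computation is in the log domain: 61 p-values of $10^{-300}$ pose no
underflow problem.

Because the SNP tests are correlated through LD, significance is assessed
by Monte Carlo: draw $Z_b \sim \mathrm{MVN}(0, R)$ with $R$ the genotype
correlation matrix estimated over founders (pairwise-complete, eigenvalue-
clipped to positive semidefinite when needed), convert to two-sided
p-values, apply the same weights, and estimate

$$p_{\text{gene}} = \frac{1 + \#\{W_b \le W_{\text{obs}}\}}{B + 1},$$

the add-one estimator, never exactly zero (default $B = 50{,}000$ draws).
For the unweighted, independent case the package also carries the exact
closed-form tail probability of the truncated product, used throughout the
tests as an independent oracle for the Monte Carlo machinery.

The gene-family stage combines the gene-level p-values (uniform weights,
same $\tau$) and reuses the *same* SNP-level ensemble: within the ensemble,
each draw's gene statistics are converted to rank-based null gene p-values,
so between-gene LD -- in particular the CHRNA3/A5/B4 cluster on one
chromosome -- propagates into the family-stage null without a nested
$B^2$ simulation.

### Why uniform weights are the default

The natural "effect size" weight from the single-SNP stage is $|b| =
|U/V| = |Z|/\sqrt{V}$, which is monotone in the evidence against the null.
Weights must be frozen at their observed values when evaluating null draws
(the ensemble contains no per-draw effect estimates), and freezing a
quantity that is itself large exactly when the observed p-value is small
couples the observed statistic to the null ensemble: in our null
experiments the gene- and family-level rejection rates ran well above the
nominal level under frozen $|b|$ weights, while the unweighted statistic
was calibrated (the test suite's calibration experiment asserts the
binomial bounds for the uniform default). The package therefore defaults to
`weight_mode = "uniform"`; `"abs_effect"` remains available for descriptive
sensitivity analyses, with this caveat documented. The calibration
experiment in `tests/testthat/test-acceptance.R` is the template for
reproducing the comparison: rerun its replicate loop with
`combine_config(weight_mode = "abs_effect")` and compare rejection rates.

A related caution: the truncated product is discontinuous in its inputs.
Two moderate p-values just below $\tau$ give $W \le \tau^2$, which already
beats a single very extreme gene; joint evidence and single-gene evidence
are deliberately different things under this statistic.

## Multiple-testing control

Storey q-values scale the Benjamini--Hochberg step-up by an estimate of the
null proportion: $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$
over $\lambda = 0.05, \dots, 0.95$, smoothed by a cubic polynomial least-
squares fit and read off at $\lambda = 0.95$, clamped to $(0,1]$ (lower
bound $1/m$ with a warning; fewer than 10 p-values fall back to
$\hat\pi_0 = 1$). A cubic polynomial was chosen over spline machinery
because the difference is negligible at $m = 61$ and it keeps the estimator
transparent. With $\hat\pi_0 = 1$ the q-values equal BH adjusted p-values
exactly, a property the tests verify on random vectors. Whether correction
should span traits jointly ($4 \times 61$ tests) or per trait (61) is a
design question the package leaves as `correction_scope`; the default is
per trait, and significance flags use $q < 0.05$.

## The synthetic study generator

The generator is first-class, tested code; it defines the conditions under
which every downstream claim is verified.

* **Pedigrees.** Each of 94 extended families is a three-generation chain:
  a founder couple, their children (of whom five marry in founder spouses),
  and grandchildren -- about six offspring-bearing nuclear units per
  family, matching the multiplex design. Third-generation sibship sizes are
  drawn from a small range and nudged deterministically so the total member
  count is exactly 3,665.
* **Founder haplotypes.** Alleles arise by thresholding a latent
  multivariate normal vector at the quantile of each SNP's minor-allele
  frequency. Within a gene block the latent correlation of adjacent SNPs is
  solved by numerical integration so the *allelic* correlation hits the
  target (default 0.6, a strong but realistic within-block LD); non-
  adjacent pairs follow the implied first-order path products, and blocks
  are independent. Thresholded binary variables cannot reach arbitrary
  correlations when frequencies differ, so unattainable targets fail
  loudly, naming the block; the bundled manifest uses frequencies clustered
  within blocks, the realistic pattern inside an LD region.
* **Gene drop.** Founders draw two pool haplotypes; each meiosis recombines
  with per-interval crossover probability 0.01 within a gene and 0.5 across
  genes/chromosomes. Output is additive 0/1/2 coding, Mendelian-consistent
  by construction.
* **Traits.** Each trait is `covariates + genetics + family effect +
  correlated noise` on the log scale, exponentiated so observed traits are
  right-skewed and the pipeline's log transform restores linearity. Total
  log-sd is split 30% shared family effect / 70% residual; residual noise
  is correlated across traits (BMI--WC 0.85, WC--WHR 0.70, etc., chosen as
  plausible values -- the source design reports no trait correlations, so
  these are the package's own defaults). Covariates (age by generation,
  sex, centre assigned by family, smoking, alcohol, steps/day, energy
  intake, a 3-level socioeconomic stand-in, diabetes) are generated
  independently of genotype, so any genotype--trait association flows only
  through the configured effects. Fifteen members lose their smoking
  status and ten more a covariate, so the exclusion filter reproduces the
  3,665 − 15 − 10 = 3,640 accounting.
* **Ground-truth effects.** The default places additive effects at three
  CHRNA5 SNPs on the two abdominal traits only (WC and WHR), none on BMI or
  %BF -- the qualitative signature of a gene family jointly associated with
  central but not general obesity. The per-allele effects (0.0057--0.0108
  on log WC, differing because the three SNPs differ in frequency and LD
  context) were calibrated once so each causal SNP has roughly 30% power at
  $\alpha = 0.05$ under the default design -- the regime where single-SNP
  analysis fails but joint analysis can succeed -- and the WHR effects are
  scaled by its smaller residual log-sd so both traits carry the same
  standardised signal. Note that even then the gene-family test rejects in
  only a minority of replicate studies: with seven genes in the product, a
  single gene must reach roughly $p \lesssim 0.006$ before the family
  p-value clears 0.05, so joint evidence of this strength is detectable but
  far from certain -- which is exactly why it is compared against the even
  rarer event of a single SNP surviving Bonferroni correction.
* **Determinism.** One master seed; each stage (pedigree, haplotypes,
  segregation, phenotypes, Monte Carlo ensemble) draws from its own derived
  sub-stream, so a stage can be regenerated without replaying the others.
  A fixed configuration reproduces outputs byte-identically.

What the generator does *not* emulate: coalescent or demographic realism,
centre-specific LD heterogeneity, genotype--covariate correlation (e.g. a
real smoking--genotype link), X-linked loci, genotyping error or
missingness by default, and rare variants. Passing tests therefore
demonstrate the statistical machinery under a faithful but idealised
rendering of the design, not properties of any real cohort.

## Numerical and edge-case choices

* Truncated products and their null comparisons are computed in logs end to
  end; the closed form uses `log1p`/`lgamma` and log-sum-exp.
* Monte Carlo p-values use the add-one estimator, bounded below by
  $1/(B+1)$.
* The LD matrix repairs indefiniteness by eigenvalue clipping and rescaling
  to unit diagonal, flagged on the result; exactly singular matrices (e.g.
  duplicated SNPs) use an eigen square root in place of Cholesky.
* Minor alleles are determined from founder frequencies only (offspring
  counts are the random quantity downstream and must not bias coding), with
  exact ties broken lexicographically. Mendelian-impossible offspring
  genotypes are set missing and counted rather than fatal, since call-rate
  style QC is upstream of this package.
* q-value ties are resolved stably; ordering of the input is immaterial.
* Degenerate inputs: empty haplotype pools are legal; a gene whose SNPs all
  exceed $\tau$ reports $W = 1$, $p = 1$; monomorphic SNPs get identity
  LD rows with a warning; an all-excluded phenotype table warns rather than
  errors.

## Problem sizes used by the test suite

The suite verifies calibration with 1,000 replicate null studies of 200
two-offspring nuclear families at $B = 2{,}000$ (gene, family and
single-SNP rejection rates inside exact binomial 95% bounds), and the
joint-vs-single power contrast with 100 replicates of the full default
design; the oracle comparison of Monte Carlo versus closed form runs at
$B = 100{,}000$ for 2, 7 and 61 combined p-values. These sizes are the
package's choices for a suite that runs in minutes while leaving the
binomial acceptance bands meaningful; `run_pipeline()` itself defaults to
the full $B = 50{,}000$.

## Known limitations

* Missing-parent families are excluded from the score; a sufficient-
  statistic treatment would recover them.
* The normal approximation for $Z$ is first-order; there is no exact
  small-sample option, hence the informative-family floor.
* The MVN ensemble approximates the joint null of the FBAT statistics by
  the founder-genotype correlation; tight linkage plus strong trait
  correlation between siblings could make the true correlation deviate
  slightly. The calibration experiment bounds the practical consequence.
* $\hat\pi_0$ read off at the endpoint $\lambda = 0.95$ has non-trivial
  sampling variance for small $m$; with 61 p-values per trait the q-values
  inherit it.
* The printed resolution of a Monte Carlo p-value is $1/(B+1)$; gene-level
  p-values at that floor (reported as about $2\times10^{-5}$ at the default
  $B$) mean "more extreme than every draw", not an exact tail estimate.
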