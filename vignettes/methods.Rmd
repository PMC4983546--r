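---
title: "Methods: polygenic risk, a general substance-involvement factor, and calibrated synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, a general substance-involvement factor, and calibrated synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycomorb)
```

## The question the pipeline answers

Psychiatric disorders and substance use disorders co-occur far more often
than chance, and twin studies suggest a large share of the genetic liability
to substance involvement is shared across substances. This package
implements a complete analysis chain for asking whether common-variant
polygenic liability to psychiatric disorders is associated with substance
involvement in a target cohort:

1. build polygenic risk scores (PRS) from discovery GWAS summary statistics
   at ten p-value thresholds, after variant QC and LD clumping;
2. summarize five ordinal substance-involvement measures (alcohol,
   nicotine, cannabis, cocaine, opioids; levels 0–4 from no/non-regular use
   to severe dependence) as a single standardized general-involvement
   factor, GENSUB, via a one-factor confirmatory model;
3. regress GENSUB on each thresholded PRS (OLS, incremental $R^2$ over the
   covariate block) and fit baseline-category multinomial logistic models of
   each substance's involvement level on the PRS, with 1-df Wald tests of
   odds-ratio equality between levels and GENSUB-adjusted reruns;
4. control the correlated family of tests with a label-swapping max-$|z|$
   permutation threshold.

Because the cohort that motivated this design is restricted-access, the
package ships a synthetic-cohort generator whose marginals are calibrated to
the published demographic and involvement tables, so every stage is testable
offline and the headline effect sizes can be checked by parameter recovery.

## PRS construction

Variants must pass MAF $> 0.02$, call rate $> 0.98$, and a Hardy–Weinberg
exact test at $p > 10^{-6}$ (all strict inequalities, as printed in the
reference analysis), and must lie outside the extended MHC region
(chr6:25–35 Mb), which is excluded for its long-range LD. The HWE test is
the exact conditional test: given observed allele counts, the p-value sums
the probabilities of all heterozygote counts no more probable than the one
observed, computed with a numerically stable recurrence anchored at the
distribution's mode.

Summary statistics are harmonized to the target cohort's counted allele by
id: direct matches keep the log odds-ratio, swapped alleles negate it,
strand-complement matches resolve the same way after complementing, and
strand-ambiguous pairs (A/T, C/G) are dropped — whether the original
pipeline dropped them is unstated, so this is a policy choice on the side
of safety.

Clumping is greedy and p-value-informed: the lowest-p unassigned variant
becomes an index and absorbs every unassigned variant on the same
chromosome within 500 kb whose genotype $r^2 \ge 0.10$ (computed on
pairwise-complete dosages; the generator provides no external LD panel, and
none is assumed). Ties on p break by chromosome then position so output is
order-independent. Undefined correlations (monomorphic variants) count as
zero.

The score at threshold $t$ averages $\beta_j \times$ (counted-allele
dosage) over the clumped variants with discovery $p < t$, with missing
dosages mean-imputed as twice the allele frequency — the default of the
standard scoring tool. One wrinkle: the spec'd strict inequality would make
the terminal threshold 1.0 exclude p-values exactly equal to 1, while the
threshold ladder is clearly meant to end with "all SNPs"; the terminal
threshold therefore uses $p \le 1$.

## The GENSUB factor

The five involvement levels are treated as continuous 0–4 codes and fit by
normal-theory maximum likelihood to the structure $\Sigma = \lambda\lambda'
+ \mathrm{diag}(\psi)$ (BFGS on $(\lambda, \log\psi)$ with analytic
gradients; principal-axis starts; sign fixed by $\sum_s \lambda_s > 0$).
This differs from a polychoric/WLSMV treatment a categorical-data program
might use; the continuous-ML choice is deterministic and dependency-free,
and the difference matters mainly for the absolute loading scale, not for
the rank ordering of factor scores. The printed fit of the original
analysis (CFI 0.992, RMSEA 0.106) is not reproducible without the
restricted data and may differ under this estimator.

Model fit uses $T = (n-1) F_{ML}$ with $df = 5$ for five indicators, an
independence baseline ($df = 10$), and the conventional formulas
$\mathrm{CFI} = 1 - \max(T_m - df_m, 0)/\max(T_b - df_b, T_m - df_m, 0)$,
$\mathrm{RMSEA} = \sqrt{\max(T_m - df_m, 0)/(df_m (n-1))}$. Unique
variances are floored at $10^{-4}$ times the indicator variance; a solution
pushed to the floor is flagged as a Heywood case rather than silently
accepted. GENSUB is the z-standardized Thomson regression score
$\lambda'\Sigma^{-1}(x - \bar x)$, fit once on the full cohort and reused
in every association, matching the single-factor-score design.

## Association and multiple-testing control

The PRS is z-scored before every fit so coefficients are per SD, consistent
with reporting a standardized $\beta^*$. Covariates are sex, within-sample
age quartiles (rank-based with deterministic tie-breaks), three ancestry
principal components, and study of origin, reference-coded. OLS reports the
standardized coefficient and incremental $R^2$ (full minus covariate-only);
the multinomial model is fit by full Newton–Raphson with step-halving on
the baseline-category log-likelihood (reference = lowest involvement),
converged at score max-norm $< 10^{-8}$, with covariance from the inverse
information (observed = expected under this canonical parameterization).
Wald 1-df contrasts compare PRS coefficients between involvement levels
using the joint coefficient covariance. GENSUB-adjusted reruns append the
factor score to the covariate block; a zero-variance GENSUB column reduces
to the unadjusted fit (with a warning) instead of tripping the
rank-deficiency error.

The permutation threshold applies one shared random permutation to the
sample indices of all PRS columns per iteration, refits every test in the
family, and records the maximum $|z|$; the critical value is the
$\lceil(1-\alpha) n_{perm}\rceil$-th order statistic of these maxima.
Permuting the PRS rather than the outcome preserves outcome–covariate
structure under the null (Freedman–Lane-adjacent reasoning), and the shared
permutation preserves inter-test dependence, which is what makes the
threshold family-wise valid for correlated tests. Defaults are 10,000
permutations at $\alpha = 0.05$. Permuted fits that fail to converge
contribute $|z| = 0$ and are counted in the output. The reference
analysis's cutoff ($z = \pm 3.911$) depends on the restricted cohort's
test-correlation structure and is deliberately not a reproduction target.

## What the generator emulates, and what it does not

The generator states a world and keeps it fixed:

* **Genotypes.** Haplotypes come from Gaussian-copula thresholding of
  exchangeable-correlation normals within LD blocks (default 600 SNPs in 60
  blocks, copula $r = 0.8$); two haplotypes sum to a dosage. Blocks span
  < 250 kb and sit > 500 kb apart, so a clumping window never crosses
  blocks and clumping behavior is analytically predictable in tests. MAF is
  uniform on (0.05, 0.5); missingness is MCAR at 1%, consistent with a
  call-rate filter but nothing more structured.
* **Discovery GWAS.** A random 30% of SNPs carry normal effects (sd 0.02 on
  the log odds-ratio scale — a scale the reference analysis never states,
  chosen once so that a 50,000-sample discovery GWAS has realistic
  per-SNP power); observed effects add noise with the standard large-sample
  SE $1/\sqrt{2 N p(1-p)}$.
* **Phenotypes.** The latent involvement factor is $\gamma \cdot
  \tilde G$ + standardized covariate effects + residual, scaled to unit
  variance; each substance's latent response is $\lambda_s f$ + unique
  error, discretized at thresholds set to the normal quantiles of the
  published involvement-category proportions ($n$ = 2573). Loadings default
  to 0.80 with nicotine at 0.65, mirroring the reported pattern of a
  somewhat lower nicotine loading. Covariates are calibrated to the
  published demographics: 56.2% female, age 38.67 (9.76), study sizes
  927/557/1089, PCs standard normal. Default covariate effects on the
  latent factor (sex −0.15, age −0.10, study ±0.10) are small plausible
  values chosen once; the reference analysis reports no such coefficients.

Not emulated: realistic human LD maps, imputation quality, ancestry
stratification beyond independent PC covariates, ascertainment (the real
cohort was recruited for substance dependence), and non-random missingness.
A green recovery test therefore establishes that the pipeline estimates
what the generator encodes at the stated n — not that the original
cohort's numbers are reproduced.

## Calibrated parameter recovery

The headline quantities — the PRS explaining 1.10% of GENSUB variance
($\beta^* = 0.110$ at the $p < 0.5$ threshold) — are recovery targets, not
reproductions. The recovered coefficient is attenuated twice relative to
the generator's $\gamma$: by $r = \mathrm{cor}(\mathrm{PRS}, G)$ (discovery
noise, thresholding, clumping) and by $\rho = \mathrm{cor}(\widehat{
\mathrm{GENSUB}}, f)$ (ordinal coarsening and factor-score validity; with
five $\lambda = 0.8$ indicators the continuous-data ceiling is already
$\sqrt{a/(1+a)} \approx 0.948$, $a = \sum \lambda_s^2/\psi_s$).
`calibrate_gamma()` measures $r \rho$ on pilot cohorts (n = 10,000) that
share the experiment's single fixed discovery GWAS and sets $\gamma =
\beta_{target}/(r\rho)$ *before* any acceptance quantity is measured. One
discovery GWAS is drawn per experiment and shared across the 200 replicate
target cohorts, as in the real design where one published meta-analysis is
scored in a fixed sample; redrawing the architecture per replicate would
make $r$ itself a random effect and defeat calibration. Replicate cohorts
use n = 2573. The mean recovered incremental $\hat R^2$ carries the usual
finite-sample inflation of roughly $1/n \approx 0.04$ percentage points
over the population value; this is reported as-is rather than corrected.

## Numerical choices and degenerate inputs

* Convergence: multinomial score max-norm $10^{-8}$ with step-halving;
  CFA BFGS relative tolerance $10^{-14}$; OLS via QR.
* Coefficients exceeding 30 in absolute value abort the multinomial fit
  with a separation error naming the predictor.
* Monomorphic variants: HWE p = 1, correlation treated as 0 in clumping,
  zero weight in scores only if their p-value admits them (a zero-variance
  column contributes nothing to the score either way).
* Empty threshold (no variant with $p < t$): explicit error naming the
  cutoff rather than a silent zero score.
* All randomness flows from integer seeds; each generator stage derives its
  own stream from the root seed (kept under $2^{31}$), so stages are
  individually reproducible and whole runs are byte-identical under a fixed
  config, which the manifest's md5 checksums make checkable.

## Known limitations

* Continuous-ML treatment of ordinal indicators understates loadings
  relative to polychoric methods; GENSUB scores are nonetheless nearly
  rank-equivalent.
* The exchangeable within-block LD model makes clumping almost always
  reduce a block to one index SNP; real LD produces more irregular clump
  structures.
* The permutation machinery refits multinomial families by full Newton
  iterations; at 10,000 permutations with many tests this is expensive, and
  desk-scale runs should pass `perm_family = "ols"` or a reduced `n_perm`
  explicitly (the defaults stay at the published values).
* Real-data mode expects pre-computed ancestry PCs in the phenotype table;
  PC computation and ancestry assignment are out of scope.
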