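---
title: "Random-regression genetic evaluation of 24-week egg production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression genetic evaluation of 24-week egg production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rregg)
```

## The model

Weekly egg production of a turkey hen is a longitudinal trait: a hen lays
for 24 consecutive weeks from her first egg, and both the mean curve and
the genetic control of production change along that trajectory. `rregg`
implements the random-regression (RR) animal model used for such data:

$$
y_{ijmt} = (H \times W)_{it} + (W \times AFE)_{mt} + b_t\,\mathrm{Bwt}
  + \sum_{k=0}^{3} \alpha_{kj}\,\phi_k(t)
  + \sum_{k=0}^{3} p_{kj}\,\phi_k(t) + e_{ijmt},
$$

where $y_{ijmt}$ is the egg count of hen $j$ in week of lay $t \in 1..24$;
the fixed effects are the hatch-week-of-birth by week-of-lay interaction
(contemporary groups), the week-of-lay by age-at-first-egg class
interaction (classes 29–31, 32–34, and >34 weeks of age), and a
body-weight covariate with a separate slope $b_t$ for each week of lay.
The random part regresses each hen's additive-genetic ($\alpha_{kj}$) and
permanent-environmental ($p_{kj}$) effect on normalized Legendre
polynomials $\phi_k(t) = \sqrt{(2k+1)/2}\,P_k(x(t))$, with the week grid
mapped linearly so week 1 sits at $x=-1$ and week 24 at $x=+1$. In matrix
form $y = Xb + Qa + Zp + e$ with

$$
\operatorname{Var}\!\begin{bmatrix} a \\ p \\ e \end{bmatrix}
 = \begin{bmatrix} K \otimes C & 0 & 0 \\ 0 & I \otimes P & 0 \\
    0 & 0 & R \end{bmatrix},
$$

where $C$ and $P$ are the $4\times4$ coefficient covariance matrices, $R$
is diagonal with four period-specific residual variances (weeks 1–4, 5–12,
13–17, 18–24), and $K$ is either the pedigree numerator relationship
matrix $A$ (RR-PBLUP) or the single-step matrix $H$ (RR-ssGBLUP) whose
inverse is

$$
H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\
  0 & G_b^{-1} - A_{22}^{-1} \end{bmatrix},
\qquad G_b = 0.95\,G + 0.05\,A_{22},
$$

with $G$ the VanRaden method-1 genomic relationship matrix of the
genotyped animals and $A_{22}$ their pedigree block extracted from the
full-pedigree $A$. Weekly (co)variances follow from the coefficient
matrices by the basis expansion $\Phi C \Phi'$ and $\Phi P \Phi'$, so the
weekly heritability is
$h^2(t) = \sigma^2_a(t) / (\sigma^2_a(t) + \sigma^2_{pe}(t) + \sigma^2_e(t))$.

## The basis convention is pinned by the published estimates

The package ships the published posterior-mean estimates for a commercial
turkey female line (`turkey_reference_params()`): $C$, $P$, the four
residual variances, and the weekly phenotypic means and SDs. Only the
*normalized* Legendre basis with weeks 1 and 24 mapped to $\pm 1$
reproduces the published weekly variance and heritability columns from
those coefficient matrices (an unnormalized basis puts the week-1 genetic
variance at 0.43 instead of 0.19), and only the residual period boundaries
1–4 / 5–12 / 13–17 / 18–24 reproduce the published heritabilities at weeks
13 and 18 (with a 5–13 second period, week 13 lands at 0.18 rather than
0.19). Both conventions are therefore fixed as defaults; the period
boundaries remain configurable through `residual_spec()`.

```{r anchors}
pars <- turkey_reference_params()
traj <- trajectory_parameters(pars$C, pars$P, pars$residual)
traj$by_week[c(1, 13, 18), ]
round(traj$cor_g[12, 16], 3) # genetic correlation, weeks 12 and 16
```

Two caveats that follow from working with printed (two-decimal) matrices:

* The expansion matches the published weekly genetic and PE variance
  columns to within 0.015 through week 22, but weeks 23–24 deviate by up
  to 0.026 (genetic) and 0.052 (PE). This is expected: an elementwise
  rounding error of $\pm 0.005$ in the coefficient matrix propagates to
  $\pm 0.005\,(\sum_k |\phi_k(t)|)^2 \approx \pm 0.145$ at week 24, where
  the covariates are largest and the published credible intervals are
  widest.
* The printed additive matrix $C$ has one small negative eigenvalue
  (−0.0046). Wherever positive definiteness is required — simulating
  trait values, inverting $C$ inside the mixed-model equations — the
  package uses a bent copy (`bend_matrix()`, an eigenvalue floor in the
  style of standard covariance bending), which stays within ~0.004 of the
  printed entries. Reporting and expansion use the printed values
  verbatim.

## Solving and sampling

The mixed-model equations are assembled sparsely (`Matrix`) with the
relationship inverse built by Henderson's rules including inbreeding
(Meuwissen–Luo coefficients; the sparse $A^{-1}$ is tested against the
dense inverse of the tabular $A$). Systems up to ~20k unknowns are solved
by sparse Cholesky; larger ones by preconditioned conjugate gradients with
a block-Jacobi preconditioner over the per-animal coefficient blocks. The
two solvers agree to $10^{-6}$ on overlap instances, and solutions are
checked against a dense GLS oracle on small data.

Variance components are estimated by a Gibbs sampler (`run_gibbs()`,
compiled core): location effects from Gaussian full conditionals blocked
per animal, $C$ and $P$ from inverse-Wishart full conditionals with
near-flat priors (identity scale, degrees of freedom $\dim + 2$), and each
residual variance from a scaled inverse chi-square with a flat prior
(df = −2), guarded at positivity. A Cholesky failure during sampling is
retried with diagonal jitter and counted (`pd_rejections`). The reference
chain protocol is 200,000 rounds with 20,000 burn-in and thinning 50
(3,600 stored samples); recovery tests in this package run 20,000 rounds
with 2,000 burn-in and thinning 10 on ~1,200 hens, which takes a few
minutes on one core. Highest-posterior-density intervals are the shortest
contiguous interval of the sorted samples; effective sample size uses the
autocorrelation sum truncated at the first non-positive lag. All draws go
through R's RNG, so a seed reproduces a chain bit-for-bit.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates a discrete-generation pedigree (default 8
generations, 12 sires and 110 dams per generation, 4 progeny per dam,
giving ~1,650 hens with records in a ~3,200-animal pedigree — a
desk-scale version of the source population of 7,422 hens), SNP genotypes
by gene dropping (default 2,000 unlinked loci on 10 autosomes plus a
sex-labelled chromosome, with planted low-MAF and high-missingness SNPs
to exercise QC), and weekly records built exactly from the model above
with the reference $C$, $P$ and residual periods as generating values and
the reference weekly means as the base curve.

Two design choices deserve emphasis:

* **Trait architecture.** By default the additive coefficient vectors are
  sums of marker effects over the autosomal loci,
  $\alpha_i = (d_i - 2p)'U$ with $U \sim MVN(0, C/(2\sum p_k q_k))$. In
  expectation this preserves every property of the classical pedigree-flow
  model — founder variance $C$, parent–offspring covariance $C/2$,
  Mendelian-sampling variance $d_i C$ — while making the genomic
  relationship matrix genuinely informative about Mendelian sampling. A
  purely pedigree-driven trait (available as
  `genetic_architecture = "pedigree"`) renders the SNPs independent of
  the trait, in which case single-step evaluation cannot outperform
  pedigree BLUP even in principle; the marker default is what makes the
  PBLUP-vs-ssGBLUP comparisons meaningful. The pedigree mode is used where
  its exactness helps, e.g. the plug-in-truth check that the
  Mendelian-sampling variance ratio tends to 1.
* **Continuous counts.** Egg counts are simulated on the continuous
  Gaussian scale the model assumes, so occasional values below zero occur;
  no truncation is applied, keeping recovery tests well-posed.

The simulator does not attempt realistic linkage disequilibrium (loci are
unlinked; the analysis uses only relationship matrices), selection across
generations, or the attrition pattern of real lay records beyond a
missing-at-random week rate (default 3%). Passing tests on these data
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions, not robustness to model misspecification in real
populations.

## Accuracy statistics

Two statistics compare RR-PBLUP with RR-ssGBLUP
(`validate_accuracy()`):

1. **Forward-validation correlation.** The youngest ~10% of hens (by hatch
   week, deterministic id tie-break, `floor(n \cdot 0.10)`) are masked
   during training; accuracy at week $t$ is
   $\mathrm{cor}(\widehat{EBV}_t, y^*_t)/\sqrt{h^2_t}$ over validation
   hens, with $y^*$ the phenotype corrected by the reference fit's fixed
   effects and $h^2_t$ the weekly heritability implied by the supplied
   variance components — one scale for both methods.
2. **Mendelian-sampling variance ratio.**
   $\nu(t) = \operatorname{Var}(\widehat{ms}_t) / (0.5\,\sigma^2_a(t))$
   with $\widehat{ms}_i = EBV_i - 0.5(EBV_{sire} + EBV_{dam})$ computed on
   the weekly EBV scale over animals with records and both parents known
   (sample variance, $n-1$). It needs no data partition and approaches 1
   as predictions become perfectly accurate; values slightly above 1 are
   flagged.

On simulator defaults the package's test suite asserts that the genomic
fit beats the pedigree fit in at least 8 of 10 seeds on each statistic,
computing both from the same masked fits (truth correlation on the
validation hens, $\nu$ on the training hens) so the comparison uses one
set of solutions per method and seed. The two statistics behave very
differently: $\nu$ uses every eligible trio and is smooth, and its
ordering is consistent across seeds, whereas the correlation statistic
rests on a ~165-hen validation set and is markedly noisier, so its
seed-level ordering is less reliable at desk scale — the same contrast
between the two statistics that motivates reporting both.

## Persistency and cumulative production

`ebv_trajectory()` returns weekly EBVs $\Phi\hat\alpha$, their 24-week
cumulative sum, and the persistency slope
$(\mathrm{EBV}(3) - \mathrm{EBV}(18))/16$ — peak week 3, reference week
18, divisor 16 as conventionally reported (the divisor is kept at 16
although the interval spans 15 weeks, reproducing the published
arithmetic; both weeks and the divisor are arguments). The variance of
partial sums of weekly genetic values is available through
`partial_sum_stats()`; with the reference $C$ the genetic correlation
between 16-week and 24-week cumulative production evaluates to 0.99. The
published range 0.94–0.96 for "correlations between egg production based
on 16 and 24 weeks" plausibly refers to an EBV correlation on the real
data, which is not reproducible from printed quantities; the package
exposes the genetic-correlation interpretation and does not force
agreement.

## Numerical choices and degenerate inputs

* Fixed-effect rank: all hatch-week-by-week cells present in the data are
  kept (no intercept); the first AFE class is the reference within each
  week; body weight is centered at its sample mean. Estimable functions
  are unaffected; EBVs are invariant to constant body-weight shifts
  (tested).
* Unknown parents are treated as draws from one base population;
  Henderson's $A^{-1}$ rules use $d_i = 0.5 - 0.25(F_s + F_d)$, dropping
  unknown-parent terms ($0.75 - 0.25F$ with one parent known, 1 with
  none).
* QC order is call rate → autosome → MAF, with MAF computed on the
  observed (post-call-rate) dosages and missing calls then mean-imputed to
  $2\hat p$; a SNP's logged reason is the first filter it fails. A MAF
  exactly at the threshold passes. An optional per-animal call-rate filter
  exists and is off by default, mirroring the ambiguity in typical panel
  pipelines about animal-level exclusions.
* Ties and degeneracies: empty genotype set makes $H^{-1} = A^{-1}$
  exactly (and ssGBLUP solutions collapse to PBLUP, tested to $10^{-8}$);
  a singular blended $G$ is prevented by the 0.95/0.05 blend; constant
  EBVs make the validation correlation undefined and are reported missing
  rather than zero.

## Problem sizes used by the shipped checks

The test suite runs the full pipeline at reduced but honest scales chosen
once: oracle equivalences on pedigrees of up to 200 animals, a dense GLS
cross-check on 30 hens, Gibbs recovery on ~1,200 hens with 20,000 rounds,
and the ten-seed method comparison on the generator defaults (~1,650 hens,
~960 genotyped animals, 2,000 SNPs). The acceptance script recomputes the
genetic correlation between weeks 12 and 16 from the reference additive
matrix — a deterministic quantity — and reports it as computed.

## Known limitations

Single-trait analyses only (no multi-trait index over production,
persistency and delay time); no genetic groups or metafounders; no
APY-style approximations for very large genotyped sets (dense $G^{-1}$
limits the genotyped count to a few thousand); REML estimation is not
provided — variance components come from the Gibbs sampler; and the
simulator's idealized genetics mean real-data behaviour (LD structure,
selection, non-Gaussian counts) is out of scope for the shipped tests.
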