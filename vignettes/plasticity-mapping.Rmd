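---
title: "Mapping transgenerational phenotypic plasticity QTLs with plastmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transgenerational phenotypic plasticity QTLs with plastmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmap)
```

## The experimental design and its traits

`plastmap` analyses a reciprocal two-generation light experiment on a
recombinant inbred line (RIL) panel. Parental RILs grow under high (H) and
low (L) light; seeds from each maternal environment are grown again under
both lights, giving treatments HH, HL, LH, LL. Leaf number is counted
weekly from week 1 to week 8, with 20 replicate plants per RIL per
treatment; replicate means are the line's trait values.

Plasticity is a *time-course* trait: for RIL $i$ with trajectories
$x_i(t)$ and $y_i(t)$ in two treatments,
$z_i = (x_i(t_1)-y_i(t_1), \dots, x_i(t_T)-y_i(t_T))$. The seven contrasts
(`plasticity_contrasts()`) split plasticity into within-generational
(pWPP, oWPP_H, oWPP_L), transgenerational (TPP_H, TPP_L) and maternal
(MPP_H, MPP_L) forms. Their algebra is exact by construction; for any RIL
present in all panels, `TPP_L - TPP_H = MPP_L + oWPP_H - pWPP` and
`MPP_L + oWPP_H = LL - HH`, which the test suite asserts at machine
precision.

Sign conventions follow the contrast table exactly (e.g. pWPP has minuend
L), so positive parental plasticity means more leaves under low light.

## The likelihood

At SNP $s$ with $J_s$ genotype classes of sizes $n_j$, the trait vectors
are modelled as $T$-variate normal with a class-specific mean curve and a
shared covariance:

$$L_s(z) = \prod_{j=1}^{J_s}\prod_{i=1}^{n_j} f(z_i;\, \mu_j, \Sigma_s).$$

**Mean curves.** Leaf-number growth is S-shaped, so each environment's
genotype mean is logistic, $\mu^e_j(t) = a_e/(1+b_e\,e^{-r_e t})$ with
asymptote $a$ (leaves), initial-growth shape $b$ and specific growth rate
$r$ (per week); the trait mean is the difference of the two component
curves, six parameters per class. The week index enters as the raw integer
week (1..8), matching measurement from one week after planting. Only the
difference curve is identified from $z$ alone; the component curves are
initialised from logistic fits to the grand means of the two source panels
(which `compute_plasticity()` always carries) refined by a direct
least-squares fit of the difference curve, and only the difference-curve
quantities (e.g. the asymptote gap $a_x - a_y$) are reported as estimands.

**Covariance.** Within one environment, longitudinal residuals follow a
first-order structured antedependence model, SAD(1):
$\Sigma(t_1,t_2) = \nu^2\,\phi^{t_2-t_1}(1-\phi^{2t_1})/(1-\phi^2)$, with
nonstationary variance from two parameters, determinant $\nu^{2T}$ and a
tridiagonal inverse in closed form (`sad1_covariance()`, `sad1_inverse()`,
`sad1_determinant()`; both closed forms are tested against generic linear
algebra). Because the two environments are independent, the covariance of
the difference trait is the *sum* of two SAD(1) matrices
(`composite_covariance()`, four parameters); the sum has no closed-form
inverse, so generic Cholesky factorisation is used wherever it appears.

**Test.** The null model has a single mean curve ($J=1$). The statistic is
$LR = 2(\log L_1 - \log L_0)$. Because the null model ignores genotype, it
is fitted once per trait (and re-fitted only for the reduced RIL subsets
that arise when a SNP's small classes are dropped); this is numerically
identical to re-estimating it per SNP. The genome-wide 5% threshold is the
0.95 quantile of the maximum LR over 100 permutations that reshuffle whole
RIL phenotype vectors against the genotype rows, preserving the temporal
covariance while breaking all marker-trait association. Empirical per-SNP
P values are the fraction of permutation maxima at or above the SNP's LR;
asymptotic chi-square P values are deliberately not used, and the paper's
printed P values are not expected to be reproducible.

## Numerical strategy

Each fit alternates two blocks, both by Nelder–Mead on transformed
parameters (logs for $a,b,r$ and the covariance scale; $\tanh$/logistic
for $\phi$ and the environment mixing weight):

1. *mean block* — each class's six curve parameters are optimised under the
   current $\Sigma$ (a generalised least-squares criterion evaluated from
   per-class sufficient statistics, so the cost is independent of the
   number of RILs);
2. *covariance block* — the two $\phi$'s and the mixing weight are
   optimised with the overall scale profiled in closed form.

The alternative fit starts exactly at the null solution, so $LR \ge 0$
holds by construction; a residual negative value would only indicate a
numerical fault and is clipped with a warning. Single-SNP fits
(`fit_null()`, `fit_alternative()`) run up to six rounds of the two blocks
(300/120 function evaluations per block, relative tolerance $10^{-7}$).
Genome-wide scans use one warm-started round per SNP with smaller budgets
(70/40 evaluations); because the permutation scans run the *same*
procedure, the threshold calibrates whatever bias the shorter optimisation
introduces, and the measured genome-wide type-I rate stays near the nominal
5%. Class filtering uses $n_{\min} = 5$; classes below it are dropped and
their RILs excluded for that SNP, and residual heterozygotes are retained
as a third class when frequent enough.

Degenerate inputs are handled explicitly: constant trajectories collapse
to the flat-curve limit of the logistic ($b$ at its lower bound);
non-positive-definite covariance proposals are rejected inside the
optimiser; monomorphic SNPs give $LR = 0$; SNPs with no class reaching
$n_{\min}$ are skipped with a machine-readable reason. Ties in the BIC
selection below are broken toward the smaller module count, and logistic
fits break RSS ties toward the smaller asymptote.

## Treatment-level summaries

"Asymptotic leaf number" is operationalised as the fitted logistic
asymptote $a$ per RIL (the week-8 value if a fit fails; failures are
logged, not fatal), with across-RIL mean and standard error reported per
treatment. The contrast-level significance summaries use a two-sided
one-sample t test of mean asymptotic plasticity against zero and Welch
two-sample t tests between contrasts, with Benjamini–Hochberg adjustment
across the whole family and a compact-letter display derived from the
adjusted pairwise matrix. The source experiment never names the test
behind its significance letters; Welch-with-BH is this package's choice,
recorded in the output metadata, and no attempt is made to match printed
P values.

## QTL modules

A significant SNP's effect curve is its genetic standard deviation (GSD),
$g_s(t) = \sqrt{\tfrac1n\sum_j n_j \mu_j(t)^2 - \big(\tfrac1n\sum_j n_j
\mu_j(t)\big)^2}$, the class-size-weighted standard deviation of the
fitted genotype means — invariant to class relabelling and identically
zero for one class. Curves are clustered with the mixture
$L(g) = \prod_s \sum_l \pi_l f_l(g_s; u_l, \Sigma)$: module means are
Legendre polynomials of order 4 (five coefficients, flexible but smooth on
eight points), and $\Sigma$ is a single SAD(1) matrix shared across
modules, as the mixture's unsubscripted $\Sigma$ suggests (a per-module
covariance is noted as an option but off by default). EM uses k-means
initialisation, ten starts, closed-form GLS updates for the module curves,
a profiled innovation variance with a 1-D search in $\phi$, and stops at a
relative log-likelihood change of $10^{-8}$ or 500 iterations; the
observed-data log-likelihood is asserted non-decreasing at every
iteration. The module count minimises
$BIC = -2\log L + d\log S$ with $d = L(\text{order}+1) + 2 + (L-1)$.

Clustering operates on GSD curves because that is the effect summary the
method defines; a signed two-class effect curve would also be possible but
is not the default. Gene-set annotation of modules is out of scope; member
SNPs are exported as BED (0-based, half-open) for external annotation
tools.

## What the generator emulates — and what it does not

`simulate_ril_genotypes()` builds the panel the study describes: two
founders, ten generations of selfing (F10), gametes formed by a Markov
walk with Haldane recombination fractions $r = (1 - e^{-2d/100})/2$ (no
interference — standard for selfed RIL construction), residual
heterozygotes retained with frequency $(1/2)^9 \approx 0.2\%$, allele
frequencies near 1/2, and linkage decaying with map distance. The default
fixture is 100 RILs, 5 chromosomes × 400 markers, 8 weekly time points, 20
replicates and 3 planted QTLs; all seeds are explicit.

`simulate_trajectories()` draws each replicate as a logistic mean plus
SAD(1) noise. Planted QTLs override the treatment baseline with
genotype-specific curves (deviations add when several QTLs touch one
treatment). Maternal effects are encoded purely through treatment-specific
baselines — there is no explicit epigenetic state variable, because the
design measures maternal effects only through treatment contrasts. The
default baselines reproduce the qualitative pattern of the study system:
parental plasticity of about +7 leaves (L − H), offspring plasticity of
about +4 (maternal L) and +2 (maternal H), positive transgenerational
plasticity stronger under maternal H, and maternal plasticity larger in
the high-light offspring environment. Noise defaults
($\phi \approx 0.8$, $\nu^2 \approx 2.5$–$3$ leaves², i.e. per-plant
late-stage SD near 3 leaves) are what a greenhouse leaf-count series
plausibly shows.

The generator deliberately omits polygenic background variation,
genotype-by-replicate interaction, measurement dropout patterns and any
sequence-level process. Passing tests therefore demonstrate that the
estimators recover the model they assume at realistic sizes and that the
permutation calibration controls genome-wide error under that model — not
that real *Arabidopsis* data meet those assumptions, and the real study's
QTL counts (which depend on an unreleased data set) are not reproduction
targets.

## Problem sizes used by the test suite

Unit tests run on panels of 2–80 RILs. The property suite uses the scales
the package treats as its reduced reference conditions: parameter recovery
at 100 RILs × 200 SNPs with a planted asymptote gap of 10 leaves (median
relative error ≤ 15% over 20 replicates); genome-wide type-I error at 50
RILs × 200 SNPs × 100 permutations over 100 scan replicates (observed rate
must lie in [0.02, 0.10]); power at 3 planted QTLs among 200 SNPs × 100
RILs (all three detected in ≥ 90% of 20 replicates); clustering recovery
on 60 curves from 3 families over 10 runs. `scripts/acceptance.R` runs the
full desk-scale study (100 RILs × 2000 SNPs) end to end.

## Known limitations

* The component curves of a difference trait are not identified
  individually; only difference-curve functionals should be interpreted.
* The asymptote of a logistic fitted on eight weekly points is an
  extrapolation; its sampling error dominates the ~8–15% relative error
  seen in gap recovery.
* With strong local linkage, neighbouring SNPs of a true QTL are also
  genome-wide significant; the significant set counts SNPs, not merged
  loci, and BIC on LD-correlated effect curves tends toward the upper end
  of the module range.
* Permutation thresholds inherit Monte-Carlo error from 100 permutations;
  empirical P values below 1/100 are reported as 0 and floored only for
  plotting.
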