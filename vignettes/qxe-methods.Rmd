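---
title: "Detecting QTL-by-environment interactions with integrated-kernel mixed models"
author: "qxescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting QTL-by-environment interactions with integrated-kernel mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qxescan)
```

## The problem

In multi-environment plant trials the effect of a quantitative trait locus
(QTL) often depends on the growing environment: a locus may act equally
everywhere (*persistence*), more strongly in one environment
(*divergence*), only in one environment (*convergence*), or in opposite
directions (*crossover*). A genome-wide association study (GWAS) that
ignores this structure misses convergence and crossover loci entirely,
while a naive per-environment analysis wastes the shared information and
multiplies the testing burden.

`qxescan` fits one unified linear mixed model per marker,

$$ y = T t + S s + f_{\mathrm{Fixed}}(x) + u_K + \varepsilon, $$

where $y$ stacks all observations (genotype × trial), $T t$ carries one
population mean per trial (there is deliberately no global intercept, so
the trial indicators stay full-rank), $S s$ holds leading
principal-component scores of the genotype matrix as population-structure
covariates, $f_{\mathrm{Fixed}}(x)$ is the marker term under test, and
$u_K$ is a background polygenic effect with an *integrated* covariance
kernel described below.

## Marker parameterisations and tests

Three fixed-effect parameterisations of a marker dosage $x \in \{0,1,2\}$
are supported, with $\pi_l$ the indicator of environment $l$ and $L$
environments:

* **additive main**: $x\beta$ — one environment-independent effect;
* **AMMI-type**: $x\beta + \sum_l (\pi_l \circ x)\gamma_l$ — a main effect
  plus per-environment deviations (the classical additive-main-effects /
  multiplicative-interaction decomposition applied to a single locus);
* **GGE-type**: $\sum_l (\pi_l \circ x)\zeta_l$ — one coefficient per
  environment, scoring main and interaction effects together.

Likelihood-ratio tests compare maximum-likelihood fits of nested designs
sharing the same kernel: the *all-terms* tests compare each
parameterisation against the marker-free model (df 1, $L+1$, $L$), and
the *interaction* tests compare AMMI-type and GGE-type against the
additive-main model (df $L$ and $L-1$). Maximum likelihood, not REML, is
used because the compared models differ in their fixed effects. Because
the AMMI-type and GGE-type designs span the same column space, their
all-terms deviances are identical marker by marker; the AMMI-type test
simply spends one more degree of freedom, which systematically deflates
its p-values. This is the numerical reason the GGE-type tests are the
package default. Per-environment effect sizes $\hat\theta_{il}$ and Wald
tests ($W = \hat\theta^2/\mathrm{var}(\hat\theta)$, df 1) are reported
from the GGE-type generalised-least-squares fit, whose coefficients are
the only separately identified per-environment effects; the AMMI design
is rank-deficient by construction (its main column is the sum of its
environment columns) and is fitted with a minimum-norm pseudoinverse
convention, with test df taken from the ledger above rather than the
column count.

## Background kernels and the integrated random effect

The background genetic covariance is built from the genomic relationship
matrix (GRM)
$$ G_{jk} = \sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}, $$
optionally divided by the marker count (default on; the kernel scale is
absorbed by the variance components, and a test asserts that rescaling
the GRM leaves every $-\log_{10}p$ unchanged). With $B = Z_G G Z_G'$ the
observation-level genomic kernel, the schemes are

| scheme | components |
|---|---|
| `G` | $B$ |
| `G+GE` | $B$, $B \circ Z_E Z_E'$ |
| `G+GT` | $B$, $B \circ Z_T Z_T'$ |
| `G+GE+GT` | all three |
| `G+perTrial` | $B$ plus one block $B \circ z_{tr} z_{tr}'$ per trial |

The Hadamard masks make the genotype-by-environment (GxE) component
independent between environments with a common variance, and likewise the
genotype-by-trial (GxT) component between trials; the per-trial scheme
allows a different variance (hence heritability) in every trial.

Rather than carrying several random effects through every marker fit, the
variances $\sigma^2_r$ are estimated **once per trait** on the marker-free
model by average-information REML, converted to weights
$w_r = \hat\sigma^2_r / \sum_r \hat\sigma^2_r$ (the residual is excluded
from the normalisation), and collapsed into one integrated kernel
$K = \sum_r C_r w_r$. Each marker fit then profiles a single variance
ratio $h = \sigma^2_K/(\sigma^2_K + \sigma^2_\varepsilon)$ on the
eigenbasis of $K$: one $O(n^3)$ eigendecomposition per trait and scheme,
then $O(nq^2)$ per marker.

## Significance, inflation and evaluation

Genome-wide significance uses q-values (Storey–Tibshirani, $\pi_0$
estimated with a smoothing spline over a $\lambda$ grid), computed per
test family; below 100 p-values the Benjamini–Hochberg adjustment is used
instead. The genomic inflation factor is the median-based
$\lambda_{GC} = \log_{10}(\mathrm{median}\ p)/\log_{10}(0.5)$, which is 1
when the observed median matches the uniform null. Simulation scans are
scored against the truth by recall, precision, the harmonic-mean
F-measure, and the area under the ROC curve computed as the Mann–Whitney
pair-win probability with ties at one half (an independent trapezoidal
integration is kept as a test oracle).

## The phenotype simulator

`simulate_phenotype()` draws
$$ y = Q_a q_{tr} + (u_G w_G + u_{GE} w_{GE} + u_{GT} w_{GT})/\omega
     + \varepsilon/\varphi $$
on a balanced trials-nested-in-environments design. Defaults encode the
study conditions: 3 major QTLs, background weights $1:1:1$, target
per-QTL variance fraction 0.1 and broad heritability 0.5, two
environments with two trials each, and per-environment effect multipliers
of $(1,1)$, $(0.5,1)$, $(0,1)$ and $(-1,1)$ for persistence, divergence,
convergence and crossover. Synthetic genotype panels come from a
Balding–Nichols generator (ancestral frequencies uniform on
$[0.1, 0.9]$, default two subpopulations at $F_{st} = 0.1$ — a realistic
degree of structure for a breeding panel — and a uniform 12-chromosome
centimorgan map), with the MAF-filter refill guaranteeing the requested
marker count.

Design choices worth stating explicitly:

* **Calibration on the drawn sample.** $\varphi$ is solved (inner root
  search) so the realized genetic fraction of variance equals the
  heritability target given $\omega$, and $\omega$ is solved (outer root
  search) so the realized per-QTL variance fraction equals its target;
  both to $10^{-6}$ on the sample quantities, so every replicate realises
  its targets essentially exactly. If the background components carry no
  variance, $\omega$ is irrelevant and only the heritability is
  calibrated.
* **Unit-variance QTL columns.** The selected QTL dosage columns are
  centred and scaled at the genotype level before effects are applied, so
  the single scalar $\omega$ can make *every* QTL realise the same pooled
  variance fraction, not just their mean. Realized per-trial fractions
  still vary with the environment multipliers (and are exactly zero in
  the null environment of the convergence condition).
* **QTL placement.** QTL markers are drawn uniformly among markers with
  MAF ≥ 0.2 and kept at least 5 cM apart (or on different chromosomes) so
  truth signals stay distinct.
* **Per-trial effects.** Trials sharing an environment receive bitwise
  identical QTL effects — the definition of an environment here.

What the generator does *not* emulate: linkage-disequilibrium decay along
the map (markers are drawn independently), dominance and epistasis,
unbalanced or incomplete trial designs, and environment-specific residual
variances. Passing tests on these fixtures therefore demonstrate the
statistical machinery under the stated reaction-norm conditions, not
robustness to every feature of real multi-trial data.

## Numerical choices

* AI-REML starts from an equal split of the phenotypic variance, takes
  two gentle EM warm-up updates before switching to average-information
  (Newton) steps with step-halving, projects negative proposals onto a
  small non-negative floor, and stops after two consecutive
  near-stationary updates (relative log-likelihood change below
  $10^{-10}$ *and* relative parameter change below $10^{-7}$, at most 100
  iterations). The tight stop rule is what makes the kernel weights
  reproducible to $10^{-6}$ under GRM rescaling.
* Variance components can legitimately converge to the zero boundary
  (e.g. the single `G` component on a crossover replicate, where the
  genotype-consistent signal cancels). If *all* genetic components are
  zero the weights are undefined; `estimate_kernel_set()` then keeps the
  kernel shape with equal weights and warns, while the per-marker ratio
  profile can still shrink the kernel contribution to zero.
* The per-marker profile uses Brent search for $h$ on
  $[10^{-6}, 1-10^{-6}]$ with tolerance $10^{-9}$; a ridge of
  $10^{-8} \cdot \mathrm{trace}(K)/n$ keeps $K$ numerically positive
  definite before eigendecomposition.
* Deviances are clamped at zero (with a warning beyond $-10^{-6}$);
  $-\log_{10}p$ is computed on the log scale and capped at 300. Markers
  with no dosage variance are reported untestable; an environment in
  which a marker is monomorphic gets a missing effect size and no Wald
  test.

## Scaled benchmark sizes

The replicated checks in the test suite and the acceptance script run a
scaled-down version of the full simulation study: 96 genotypes, 500
markers, 2 environments × 2 trials, and 20 replicates per condition
(the calibration check uses a single 2,000-marker replicate). These sizes
were chosen as the package's standard desk-scale benchmark; the
`benchmark` CLI subcommand exposes the replicate count, marker count and
scheme list for larger runs. At this scale the mean interaction-test AUC
under persistence sits near 0.5 with a replicate standard deviation of
about 0.13 — with only three truth markers per replicate the per-replicate
AUC is intrinsically coarse, so 20-replicate means still move by a few
hundredths between seeds.

## Known limitations

* Environments and trials are categorical; continuous environmental
  covariates (weather-driven reaction norms) are out of scope.
* Weights are frozen at their marker-free estimates (the standard
  two-stage shortcut); no per-marker multi-kernel re-estimation.
* Wald variances come from the ML generalised-least-squares covariance at
  the fitted variance ratio, not from a REML fit.
* The Storey $\pi_0$ estimator needs a few hundred p-values to be stable;
  small scans fall back to Benjamini–Hochberg automatically.

## A minimal session

```{r example, eval = FALSE}
geno <- generate_genotypes(m = 96, I = 500, Fst = 0.1, seed = 1)
design <- complete_design(geno, c(A = 2, B = 2))
spec <- simulation_spec("crossover", seed = 2)
sim <- simulate_phenotype(geno, design, spec)

scan <- run_scan(geno, sim_phenotype_table(sim), scheme = "G+GE+GT")
evaluate_scan(scan, sim$truth)
```
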