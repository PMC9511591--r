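---
title: "Two-stage heritability analysis for three-generation families: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage heritability analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famh2)
```

## The scientific problem

Cardiovascular risk markers — blood pressure, arterial stiffness (pulse
wave velocity), carotid intima-media thickness (cIMT) and left
ventricular mass indexed to body surface area (LVMI) — tend to resemble
each other within biological families. `famh2` quantifies that
resemblance in maternal-line three-generation cohorts (grandmother,
mother, child), a design in which fathers are unobserved and each family
contributes three biological pairings: grandparent–parent,
parent–grandchild, grandparent–grandchild.

The analysis is deliberately two-staged. Stage 1 asks, trait by trait
and pairing by pairing, whether the offspring trait is associated with
the parental trait at all, using a randomisation test that makes no
distributional assumption and is honest at small sample sizes. Stage 2
then estimates, for traits that show transmission, how much of the
phenotypic variance is attributable to genome sharing — the broad
heritability $h^2$ — under a variance-component linear mixed model,
with three estimators (ReML, Gibbs, HMC) whose agreement is itself a
useful robustness check.

## Stage 1 — the random family method

For one trait and one generation pairing, each family contributes a pair
$(z_i, y_i)$: parental and offspring trait values. The model is ordinary
least squares,

$$ y_i = \beta_0 + \tau z_i + \beta' X_i + \epsilon_i, $$

where $X_i$ holds the offspring's covariates and $\tau$ is the
transmission slope of interest. Pressures, PWV and cIMT are adjusted for
age, height, weight and sex; LVMI for age and sex only, since it is
already indexed to body surface area. Inference on $\tau$ is by
restricted resampling: the parental exposure vector is re-assigned to
offspring by a uniformly random *derangement* — a permutation with no
fixed point, so no resampled "family" reproduces a biological pairing —
and $\tau$ is refitted each time. With $c$ the number of resampled
slopes at least as extreme as the observed one ($|\tau^{(b)}| \ge
|\tau_{obs}|$, ties counting as exceedances), the empirical p-value is
exactly

$$ p = c / n $$

with no $+1$ smoothing, so $p = 0$ is possible and $p$ is reported
together with $c$ and $n$. The default $n$ is 5000 re-pairings.

Design choices that were genuinely open:

* **Derangement vs unrestricted permutation.** "Random family units"
  are read as non-biological pairs, hence the derangement constraint by
  default; unrestricted permutation is available via
  `restricted = FALSE` for sensitivity analysis. At $n = 65$ pairs the
  two differ negligibly (a uniform permutation has on average one fixed
  point).
* **Whose covariates enter $X$.** The offspring's: they predict the
  outcome. Parent-side columns can be permuted together with the
  exposure via `permute_with` if a parental covariate is added.
* **Degenerate covariates.** In the parent-on-grandparent rows every
  offspring is a woman by design, so sex carries no information and
  would make the design singular; `extract_pairs()` drops covariates
  that are constant on the offspring side of a pairing. An explicitly
  supplied constant covariate in `fit_tau()` is still an error naming
  the column, as is a constant exposure.
* **Seeds.** A master seed is expanded into per-row seeds via
  `derive_seeds()` (seed the RNG once, draw uniform integers), so any
  single row is reproducible in isolation.
* **Kernel density displays** use a Gaussian kernel with Silverman's
  rule-of-thumb bandwidth. The bandwidth is diagnostic only; no p-value
  depends on it.

Calibration: under an exchangeable null the test attains its nominal
size. Without the $+1$ correction the rejection rule $p < \alpha$ has
exact size $\lceil \alpha n \rceil / (n + 1)$ for continuous statistics
— 0.0499 at $\alpha = 0.05$, $n = 500$ — which the acceptance suite
verifies by simulation (1000 datasets of 65 exchangeable pairs).

## Stage 2 — variance components and $h^2$

For a trait passing Stage 1, all measured individuals enter the linear
mixed model

$$ y \mid X \sim N(X\beta, \; G\sigma_g^2 + I_n\sigma_e^2), $$

where $G$ is the genetic relatedness matrix derived from the pedigree
($G = 2\Phi$, twice the kinship matrix: 1 on the diagonal, 1/2 for
parent–offspring, 1/4 for grandparent–grandchild, 0 across families)
and age is the only fixed covariate. The trait and age are standardized
to mean 0, variance 1 before estimation — this improves the geometry for
the samplers and puts the variance components on the interpretable
scale $\sigma_g^2 + \sigma_e^2 \approx 1$. Heritability is

$$ h^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2}. $$

All three estimators work in the eigenbasis of $G$ ($G = UDU'$), where
the covariance is diagonal: $\tilde y = U'y$, $\tilde X = U'X$,
$v_i = \sigma_g^2 d_i + \sigma_e^2$.

**ReML.** The restricted log-likelihood is profiled in
$\lambda = \sigma_g^2/\sigma_e^2$ (error variance and fixed effects
maximised analytically at each $\lambda$), bracketed on a coarse
log-grid over $\lambda \in [e^{-18}, e^{18}]$ and polished by golden
section. Boundary estimates $\hat\sigma_g^2 = 0$ are permitted;
standard deviations come from the inverse observed information
(central-difference Hessian in $(\sigma_g^2, \sigma_e^2)$) with the
$h^2$ SD by the delta method, and are reported as unavailable at the
boundary, where the Wald approximation is meaningless.

**Gibbs.** The Bayesian model adds $\beta_j \sim N(0, 1000^2)$,
polygenic effects $g \sim N(0, \sigma_g^2 G)$, and
$\sigma_g^2, \sigma_e^2 \sim \mathrm{InvGamma}(s_1, s_2)$ with
$s_1 = s_2 = 0.001$ as a conventional non-informative default (the
suite includes a prior-sensitivity check against $s = 0.01$). The full
conditionals are all standard; sampling $g$ in the eigenbasis makes its
conditional precision $I/\sigma_e^2 + G^{-1}/\sigma_g^2$ diagonal, so a
full scan costs $O(n)$ beyond two fixed $O(np)$ projections. The
production run makes 100 000 iterations and keeps the last 90 000;
per-draw $h^2$ is recorded so the posterior summary is the mean (SD) of
the ratio, not the ratio of means.

**HMC.** The polygenic effect is integrated out analytically, and
Hamiltonian Monte Carlo runs on $(\beta, \log\sigma_g^2,
\log\sigma_e^2)$ with the Jacobian correction, analytic gradients,
leapfrog integration (25 steps), and dual-averaged step size targeting
0.8 acceptance during burn-in, frozen thereafter. Divergent
trajectories are rejected and counted; more than 5% divergence after
warm-up is an error.

Numerical choices: eigenvalues are floored at $10^{-12}$ for the ReML
transform; the samplers require $G$ positive definite, which pedigree
GRMs of outbred maternal-line trios are by construction (trio block
eigenvalues $\approx$ 1.93, 0.75, 0.32); chains are initialised at
$\sigma_g^2 = \sigma_e^2 = \mathrm{var}(y)/2$, $\beta = 0$.

The model displays one genuine ambiguity in its Bayesian formulation:
a polygenic prior written with the error variance
($u \sim N(0, \sigma^2 G)$) cannot yield a separate genetic variance,
so the package implements $g \sim N(0, \sigma_g^2 G)$, which the
definition of $h^2$ requires.

During the session the two samplers were checked against exact 2-D
quadrature of the marginalised posterior (fixed effects integrated
analytically) on a 30-trio fixture; the shipped tests enforce the same
consistency as cross-estimator agreement: Gibbs vs HMC within combined
Monte-Carlo error, both within 0.1 of ReML on a shared 65-trio cohort.
Note the Gibbs sampler mixes slowly in $h^2$ (effective sample sizes of
a few hundred from 90 000 draws are normal here) — the agreement
tolerance uses ESS-based standard errors, and `summary()` reports ESS
and split-$\hat R$.

**Testing against the null.** `lrt_h2()` compares the restricted
likelihood at the optimum with the $\sigma_g^2 = 0$ profile; because the
null lies on the parameter boundary the statistic is referred to a
50:50 mixture of a point mass at zero and $\chi^2_1$. `estimate_power()`
wraps this in a design simulation: at the 65-family design it yields
about 5% rejection at $h^2 = 0$, and roughly 77–81% and 89–93% power at
$h^2 = 0.4$ and $0.5$ respectively (300-replicate runs; binomial
MC-SEs of 2–3 points).

## Pedigree relatedness

`kinship_coefficients()` implements the recursive tabular method:
processing parents before offspring,
$\phi_{ii} = (1 + \phi_{m(i)f(i)})/2$ and
$\phi_{ij} = (\phi_{m(i)j} + \phi_{f(i)j})/2$, with unknown parents
contributing zero (founder alleles unique). Inbreeding cannot arise in
maternal-line trios and an inbred self-kinship raises rather than
propagating silently. `gene_drop_kinship()` provides an independent
Monte-Carlo check by explicit allele transmission; the acceptance suite
runs it at $10^5$ replicates and requires agreement within three
Monte-Carlo SDs.

## The synthetic generator

`generate_dataset()` makes the whole pipeline runnable with no external
data. Its defaults are the study conditions: 65 maternal-line trios
(195 individuals), all-female adult generations, child sex female with
probability 36/65, generation ages centred at 56/29/7 years, and
per-measure missingness matching the cohort's completion counts (e.g.
PWV successful in 57/61/56 of 65 per generation). Breeding values flow
down the pedigree with the correct Mendelian structure for unobserved
fathers: founders $g \sim N(0, \sigma_g^2)$, one-known-parent
individuals $g = g_{mother}/2 + N(0, \tfrac34\sigma_g^2)$, so every
marginal variance is $\sigma_g^2$ and $\mathrm{Cov}(g) = \sigma_g^2 G$
exactly. Traits follow
$y = \beta_0 + \beta_{age}(age - 30) + \beta_{sex}\,male + g + e$.

Default true heritabilities (0.35 cIMT, 0.30 LVMI, 0.25 for pressures
and PWV) are motivated by the estimate ranges this kind of cohort
reports; trait locations and spreads are loosely matched to the
cohort's descriptive medians/IQRs. Exact marginal matching is a
non-goal — the analysis stages depend only on the dependence structure.
What the generator deliberately does **not** emulate: shared-household
environmental variance (so its "heritability" is purely additive,
whereas a real pedigree estimate confounds genes with shared
environment), device-level measurement protocols, and marker genotypes.
Passing tests therefore demonstrate correctness of the estimators under
the stated generative model, not unbiasedness on real cohort data.

A useful cross-module identity: with no covariates, the large-sample
regression slope of offspring on parent is $h^2/2$ and of grandchild on
grandparent $h^2/4$ (half and quarter expected genome sharing), which
the suite verifies at 20 000 families.

## Derived phenotypes

The measurement rules are implemented exactly as stated for the cohort:
the second and third of three BP readings averaged; adult BMI categories
with half-open intervals ($[18.5, 25)$ normal — avoiding a gap at
24.95); child BMI and BP categories via replaceable age/sex(/height)
reference tables (the bundled CSVs are small synthetic fixtures
demonstrating the schema, with the convention that a value at a cut-off
enters the higher category); hazardous alcohol use as AUDIT-C $\ge 3$
or total AUDIT $\ge 8$; left-ventricular mass by the ASE-corrected
Devereux cube formula $0.8 \cdot 1.04((IVS+LVID+PW)^3 - LVID^3) + 0.6$
g; BSA by Mosteller ($\sqrt{hw/3600}$) by default with Du Bois
selectable, a choice made explicit because the 95 g/m² LVH threshold is
BSA-formula sensitive; LVH by strict inequality above 95 g/m² for adult
women and above the 109.4 g/m² child 95th percentile. Derived values
propagate missingness; nothing is imputed.

## Problem sizes in the shipped checks

The test suite runs the randomisation-calibration at 1000 datasets ×
500 resamples, ReML recovery at 200 replicates of the 65-trio design,
the ReML-vs-grid comparison on a 200 × 200 dense grid over
$(\sigma_g^2, \sigma_e^2)$ at $n = 30$, sampler agreement with
10 000-iteration chains, gene dropping at $10^5$ replicates, and the
slope limits at 20 000 families; these sizes give Monte-Carlo errors
comfortably inside the stated tolerances while keeping the full suite
to a few minutes. Bayesian production settings (100 000 iterations,
burn-in 10 000) are exercised through the same code path at reduced
length.

## Known limitations

* The pedigree $h^2$ is a broad estimate: with maternal lines only and
  no household component, genetic and shared-environment resemblance
  are confounded in real data.
* Under the null, boundary-truncated ReML has a positive-part bias of
  order half the estimator SD ($\approx 0.07$ at the 65-trio design);
  bias at any fixed $h^2$ shrinks like $1/\sqrt{families}$, as the
  10×-design recovery test shows.
* The Gibbs sampler's slow mixing in $h^2$ makes short chains
  untrustworthy; use the reported ESS, or HMC, whose effective sample
  sizes are one to two orders larger per kept draw.
* Marker-based (genomic) relatedness, bivariate genetic correlations
  and ascertainment correction are out of scope.
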