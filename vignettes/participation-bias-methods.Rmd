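---
title: "Sex-differential participation bias: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-differential participation bias: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partbias)
```

## The problem

Large retrospective cohorts enroll a small fraction of their target
population, and enrollment is not random: health, behaviour, and — directly
or indirectly — genotype influence who participates. Analysis is then
conditional on participation, a common effect of many variables, which
opens collider paths. The signature symptom is that autosomal variants
become associated with biological sex *among participants*, even though no
autosomal variant causes sex. When the effects of a variant or trait on
participation differ between the sexes ("sex-differential" participation),
this spurious signal propagates into trait GWAS and into Mendelian
randomization built on the resulting summary statistics.

`partbias` simulates this mechanism end to end, provides an exact
enumeration oracle for the induced sex–genotype association, and implements
and stress-tests the correction: run the GWAS within each sex and pool the
two estimates by fixed-effects inverse-variance meta-analysis.

## The generative model

**Population.** Genotypes are minor-allele dosages $g_{ij} \in \{0,1,2\}$
drawn independently as $\mathrm{Binomial}(2, p_j)$ — unlinked variants in
Hardy–Weinberg equilibrium. Linkage disequilibrium is deliberately absent:
the bias studied here is marginal and per-variant, and LD would only blur
the accounting between a variant's own participation effect and its
neighbours'. Sex is Bernoulli with male fraction 0.5 by default.

**Traits.** Binary traits follow the conventional liability-threshold
model: liability $L_i = \sum_j b_j (g_{ij} - 2p_j) + e_i$ with
$e_i \sim N(0, 1-h^2)$, and the trait is 1 when $L_i$ exceeds
$\Phi^{-1}(1-K)$ for prevalence $K$. Effects are drawn i.i.d. normal on
standardized genotypes and then rescaled so the analytic genetic variance
$\sum_j 2p_j(1-p_j)b_j^2$ equals $h^2$ *exactly*, not just in expectation.
This makes heritability an exactly testable invariant rather than a
distributional statement, at the cost of a (negligible at 100+ causal
variants) shrinkage of effect-size dispersion.

**Participation.** Individual $i$ of sex $s$ participates with probability
$$\mathrm{expit}\!\left(\alpha_s + \textstyle\sum_j b_{s,j}(g_{ij}-2p_j)
  + \sum_t \gamma_{s,t} x_{it}\right),$$
i.e. a liability threshold with *standard-logistic* noise. The logit link
is the model on which the closed-form theory below rests, so it is the
default and the canonical generative mechanism throughout; traits keep the
probit convention because that is how liability-threshold phenotypes are
conventionally defined, and nothing in the bias mechanism depends on the
trait link. The liability-scale heritability of participation for sex $s$
is $h^2_s = V_s / (V_s + \pi^2/3)$, where $V_s$ is the variance of the
genetic linear predictor and $\pi^2/3$ the logistic noise variance;
`draw_participation_effects()` inverts this identity exactly when scaling
effects, so the identity holds analytically, not merely asymptotically.

**Calibration.** The participation rate $\pi$ (per sex) is an experimental
input, so intercepts are *solved*, not guessed:
`calibrate_participation()` root-finds $\alpha_s$ such that the mean
participation probability over the simulated linear predictors equals the
target rate, with a monotone bracket and an absolute rate tolerance of
1e-4 — well below the Monte-Carlo noise of any experiment run at these
scales. Under the `sex_independent` scenario with equal target rates the
model has a single intercept by construction, and calibration is pooled
across sexes so both intercepts are *exactly* equal; this is the
configuration in which the post-selection sex–genotype association
vanishes identically at every participation rate, and per-sex calibration
noise would otherwise blur that exact null.

## Why a sex GWAS measures the bias

Among participants, Bayes' rule gives
$$\mathrm{logit}\,P(\text{male}\mid g,\ \text{participate})
 = \mathrm{logit}\,\phi
 + \log \mathrm{expit}(\alpha_m + b_m \tilde g)
 - \log \mathrm{expit}(\alpha_f + b_f \tilde g),$$
with $\phi$ the male fraction and $\tilde g = g - 2p$. The package's
enumeration oracle (`exact_sex_effect_oracle()`) evaluates this exactly on
the six (genotype × sex) cells and fits the weighted logistic slope — the
number the simulated sex GWAS converges to as $n \to \infty$, obtained
here with no sampling at all. Two limits anchor the behaviour:

* $\pi \to 0$: $\log \mathrm{expit}(z) \to z$, so the log-odds is linear
  in dosage with slope exactly $b_m - b_f$. The sex-GWAS effect of a
  variant is the between-sex *difference* of its participation effects —
  the levels cancel.
* $\pi = 1$: no selection, slope 0.

Between the limits the oracle is exact, and the test suite verifies that
the gap $|\text{slope} - (b_m - b_f)|$ shrinks monotonically as $\pi$
falls. With sex-independent effects but *unequal* rates, the induced slope
scales linearly with the between-sex rate difference near zero — which is
why a realistic rate gap of order 1% cannot generate large apparent
participation heritability on its own.

When participation is driven by many variants at once, the per-variant
oracle is applied with intercepts calibrated to the marginal rates; the
other variants then act as additional (non-logistic) liability noise that
the single-variant enumeration does not see. The predicted inflation is
therefore an upper-bound-flavoured approximation at moderate $\pi$, and
the pi-grid runner emits the Monte-Carlo/oracle discrepancy as its own
metric rather than folding it away.

## The estimators

`logistic_gwas()` fits one maximum-likelihood logistic regression per
variant (IRLS, tolerance 1e-8, at most 50 iterations). Failures are
flagged, never dropped silently or raised as exceptions: monomorphic
variants, non-convergent fits and (quasi-)separated fits carry `NA`
statistics, and variants with any genotype-by-outcome cell under 5
(`min_count`) keep their estimates but are excluded from inflation
summaries, where unstable Wald statistics would otherwise dominate the
mean chi-squared. `linear_gwas()` is the OLS/linear-probability fallback;
on a balanced binary outcome its effects are the logistic ones times
$\approx 1/4$, which the tests check.

`fixed_effects_meta()` pools any number of strata with inverse-variance
weights; with a single usable stratum it returns that stratum unchanged,
and it can only gain information ($se_{\text{meta}} \le \min_s se_s$).
`mr_ivw()` is the standard first-order IVW estimator — a zero-intercept
weighted regression of outcome on exposure effects with weights
$1/se_Y^2$, exposure-side uncertainty ignored — with Cochran's $Q$ emitted
as an untested diagnostic.

## Does the combined GWAS adjust for sex?

This was a genuinely open design point, and the answer is scale-dependent
in an instructive way. In the rare-participation limit the participant
distribution factorizes as an exponential tilt,
$P(g, x, s \mid \text{participate}) \propto
P(g)P(s)P(x)\,e^{\alpha_s + b_s \tilde g + \gamma_s x}$, so *conditional on
sex* the trait and the genotype remain independent: a combined GWAS that
includes sex as a covariate absorbs essentially the whole marginal bias at
very low $\pi$ (it re-emerges at moderate $\pi$, where the tilt
approximation degrades). The bias the stratify-then-meta correction
targets is the *marginal* association that a scan not conditioning on the
selection-driving variable exhibits. `run_trait_gwas()` therefore keeps
sex as a default covariate (the common practice), while the correction and
MR experiments run their combined scans unadjusted by default
(`gwas$sex_covariate` in the config restores adjustment), so that the
combined-versus-stratified contrast measures the phenomenon rather than
the covariate choice. Note that covariate adjustment is not a general
substitute for stratification: it is exact only in the rare limit, only
for a correctly measured binary stratifier, and only when no
sex-by-genotype interaction is of interest.

## Experiment defaults and what they represent

The sweep runners default to a population of 100,000 individuals, 1,000
variants of which 200 drive participation, and 50 replicates — a
desk-scale stand-in for a biobank-style design in which participation is
polygenic and the tested panel is mostly null. Other defaults, chosen once
on substantive grounds:

* Allele frequencies uniform on (0.1, 0.5) in grid experiments (0.2–0.5
  where participant counts are small, keeping genotype-by-outcome cells
  populated); 0.3 fixed where a single variant is studied.
* Participation heritabilities swept as parameters; the sex-differential
  default contrasts $h^2 = 0.2$ vs 0 with between-sex effect correlation 0
  (the maximally differential case; the correlation is a config knob
  because intermediate values are equally plausible).
* Trait-on-participation effects $\gamma_m = 2$, $\gamma_f = 0$ in the
  correction and MR experiments: an odds ratio of ~7 for participation
  given the trait in men and none in women. This is the "strong,
  maximally sex-differential" end of plausible — chosen so the bias being
  corrected is unmistakably present at $\pi = 0.01$; the correction's
  performance does not depend on it.
* Participation rate $\pi = 0.01$ for bias experiments (the rare-limit
  regime relevant to national-biobank recruitment), $\pi = 0.001$ for the
  slope experiment, where the regression of estimated sex-GWAS effects on
  $b_m - b_f$ has theoretical slope 1.
* Power experiment: $\pi = 1$, significance level $5 \times 10^{-4}$, and
  a per-variant effect size placing combined-GWAS power mid-range, where a
  power difference would be most visible; 500 replicates bound the paired
  CI half-width well under 0.05.

The acceptance checks and test suite run these experiments at reduced
sizes — populations sized to deliver roughly 2,000 participants per
replicate, 20–50 variant panels for the correction/MR designs, 30–50
replicates — chosen so the whole suite completes in minutes on one core
while every Monte-Carlo tolerance (quoted per test, typically 4 standard
errors) still has margin.

Seeding: every runner takes one master seed; per-cell and per-replicate
seeds come from `derive_seed()`, a small multiplicative hash whose
products stay exactly representable in doubles and whose outputs stay
below $2^{31}$. Each emitted record carries its own seed, and reruns with
the same configuration are bit-identical.

## What the simulations do and do not show

The generator captures the mechanism — genotype- and trait-driven logit
participation with per-sex structure — but idealizes around it: no LD, no
assortative mating or population structure, no covariate measurement
error, participation decided once per individual (no attrition over
time), binary participation drivers only, and an exactly logit link.
Passing tests therefore demonstrate that the estimators behave as the
theory predicts *under the stated model*; they do not certify behaviour
under non-logit selection (a probit-style switch would be a natural
extension), continuous participation-driving variables, or real-cohort
complications such as unknown target-population denominators. The
stratify-then-meta correction itself also weakens as participation rates
grow, since its justification is the rare-participation factorization —
the oracle quantifies exactly how fast.

Known limitations worth restating: the multi-variant oracle prediction is
approximate at moderate $\pi$ (discrepancy emitted, not hidden); the
"slope equals rate difference" reading of the linear-probability scale is
reported alongside the realized rate difference rather than asserted,
because the claim's normalization is ambiguous; and MR experiments use
oracle instruments (the exposure's true causal variants), so winner's
curse — a separate bias — is intentionally out of frame.
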