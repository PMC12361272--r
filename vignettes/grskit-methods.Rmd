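---
title: "Methods: interaction-aware genetic risk scores with grskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction-aware genetic risk scores with grskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

grskit builds and evaluates a genetic risk score (GRS) for type 1
diabetes case-control data in which the dominant signal comes from HLA
*DQA1-DQB1* haplotypes, part of that signal is non-additive across
haplotype pairs, and a modest number of non-HLA SNPs add independent
information. This vignette is the package's account of the underlying
statistics: the generating and fitted models, the tunable parameters and
why their defaults are what they are, the numerical choices, and what the
simulation-based validation does and does not establish.

## The score

For individual $i$ with haplogenotype $(h_{i1}, h_{i2})$ and effect-allele
dosages $d_{ij} \in [0,2]$,

$$
\mathrm{GRS}_i \;=\; \mathrm{DQ}_i \;+\; \sum_{j \in \text{HLA-other}} \beta_j d_{ij}
\;+\; \sum_{j \in \text{non-HLA}} \beta_j d_{ij},
$$

where every $\beta$ is the natural log of a case-control odds ratio. The
DQ term follows two *exclusive* paths: if the unordered pair
$\{h_{i1}, h_{i2}\}$ has an entry in the interaction lookup table, that
score is used verbatim; otherwise $\mathrm{DQ}_i = \beta_{h_{i1}} +
\beta_{h_{i2}}$. We read the two-branch construction as exclusive (the
lookup *replaces* the additive contribution) rather than as an additive
adjustment: carriers of an interacting pair are assigned "a score based on
the interaction", and making the lookup a correction on top of the
additive term would double-count the main effects that the interaction
model already absorbs.

The composition of the lookup value is a genuinely open choice: the
interaction coefficient $\gamma$ alone, or the full fitted log-odds of the
haplogenotype (main effects at carrier doses plus $\gamma$). The default
is the full log-odds (`significant_interactions(score = "full")`), because
the additive path also measures a total log-odds relative to the reference
homozygote — the two branches then live on the same scale. The
$\gamma$-only variant is kept available (`score = "gamma"`).

## The generating model

`simulate_cohort()` draws individuals from

$$
\eta = \alpha + \beta_{h_1} + \beta_{h_2} + \gamma_{\{h_1,h_2\}}
+ \textstyle\sum_j \beta_j d_j + \beta_{\mathrm{sex}}\,\mathrm{sex}
+ \textstyle\sum_k \beta_{\mathrm{PC}_k} \mathrm{PC}_k,
\qquad \Pr(\text{case}) = \operatorname{expit}(\eta),
$$

with haplotypes i.i.d. from a frequency pool, SNP dosages
$\mathrm{Binomial}(2, \mathrm{MAF})$, sex Bernoulli(½) and PCs standard
normal, and fills fixed case/control quotas by rejection sampling. Fixed
quotas mirror how case-control panels are actually assembled; a
consequence used throughout the tests is that retrospective sampling
leaves logistic slopes invariant — only the intercept is distorted — so
single-SNP regression on the sampled cohort recovers the generating
$\beta$. The intercept is a free knob (`intercept`, default −1.5 log-odds)
with no canonical value: a case-control design implies no particular
baseline prevalence, so the parameter only controls the rejection
sampler's acceptance rate. Quotas that cannot be filled (acceptance
probability near zero) abort with a diagnostic rather than looping.

### The default haplotype pool

`default_haplotype_pool()` ships ten *DQA1-DQB1* haplotypes with
frequencies summing to 1 and per-copy log-odds chosen once to reflect the
known direction of type 1 diabetes risk in Chinese populations: DR9
(`DQA1*03:02-DQB1*03:03`) and DR4 (`DQA1*03:03-DQB1*04:01`) and DQ2
(`DQA1*05:01-DQB1*02:01`) as risk haplotypes, `DQA1*01:02-DQB1*06:02`
(DR15) and `DQA1*01:02-DQB1*05:02` as protective, and DQ8
(`DQA1*03:01-DQB1*03:02`) near-null — the notable East-Asian departure
from European cohorts. Frequencies are plausible population values, not
estimates from any specific dataset. The pool deliberately contains one
"ambiguity quartet" (`01:01/01:02 × 05:01/05:02`, all four combinations
present at unequal frequencies) so that unphased typing does not always
phase uniquely and the inference step is genuinely exercised; under this
pool roughly 3% of individuals are ambiguous double heterozygotes and the
frequency-product rule resolves almost all of them correctly (the
acceptance script reports the realized accuracy, ≈ 99.9%).

Default interaction effects plant $\gamma$ on three pairs (0.8 on
DR9×DQ2, 0.5 on the DR9 homozygote, 0.6 on DR4×DQ2); default additive
SNPs are the six published markers in `default_nonhla_snps()` with their
printed MAF and $\beta$. Default `missing_rate = 0.02` keeps the
missingness filter non-trivial while staying below its 0.05 threshold.

### LD-tagged SNPs

Tag SNPs are injected on *phased chromosomes* by symmetric allele
flipping: the tag allele equals the haplotype indicator, flipped with
probability $\varepsilon$ per chromosome. With haplotype frequency $p$
the expected phased correlation is

$$
r^2(\varepsilon) = \frac{p(1-p)(1-2\varepsilon)^2}{q(1-q)}, \qquad
q = p + \varepsilon(1-2p),
$$

which decreases strictly from 1 at $\varepsilon = 0$ to 0 at
$\varepsilon = \tfrac12$; `solve_tag_epsilon()` inverts it by bisection
(tolerance 1e−12), with $\varepsilon = 0$ exactly when the target is 1.
Flip-injection is far simpler than simulating recombination and is
sufficient for testing tag selection; it produces a single tag per
haplotype with no background LD structure among tags.

## Fitted-model choices

**QC.** Variants are dropped if monomorphic, MAF < 0.05, exact-test HWE
p < 1e−4, or missingness > 0.05 (all configurable; disabling every
threshold makes QC the identity). HWE uses the conditional exact test —
the p-value sums the probabilities of all heterozygote counts no more
likely than the observed one, given the allele counts — on dosages
hard-called to the nearest integer, and is evaluated **in controls only**
when a phenotype is supplied: risk loci deviate from HWE in cases by
construction, so testing in cases would discard real signal. Whether to
test controls only or everyone is not dictated by the score definition;
controls-only is the standard GWAS-QC practice and is what the package
does.

**Association.** All per-variant and per-haplotype tests are logistic
regressions fitted by IRLS with Wald statistics (OR = exp(β),
CI = exp(β ± 1.96·SE)). Missing dosages are mean-imputed per variant,
preserving sample size; with ≤ 5% missingness the induced attenuation is
below ~2% of β. Separation and non-convergence are flagged (fitted
probabilities within 1e−10 of 0/1, or SE > 50) and flagged fits never
report estimates; aliased columns get NA coefficients exactly as `glm`
does, which also makes scoring invariant to adding an uncarried haplotype
column. Covariates (sex, PCs) enter only if marginally associated at
p < 0.05. Significance tiers (1e−5 suggestive, 5e−8 genome-wide) are
annotations; filtering belongs to the model-building step.
Meta-analysis across cohorts is inverse-variance fixed-effect — the
natural choice for a two-cohort discovery/replication design, where
random-effects heterogeneity is inestimable — with effect-allele
orientation checked and sign-flipped on allele swaps.

**Haplotype frequencies and the 0.5% rule.** Frequencies are computed on
chromosomes (2n per group), and a haplotype is kept only if above 0.5% in
cases *and* controls. "Present in 0.5% of individuals" would be the other
reading of such a rule; chromosome frequency is chosen because every
downstream quantity (dosage, LD, tagging) is chromosome-level.

**Interactions.** Candidate haplogenotypes need ≥ 10 carriers (guards
against separation). The interaction term is the dose product for a
heterozygous pair — which, since DQ doses sum to 2, equals the indicator
of carrying the pair — and a dose-2 indicator for homozygous pairs (the
raw product, 4, would conflate with the additive dose). Each pair is
tested in its own model containing *all* kept haplotype main effects
(reference: the most frequent control haplotype, dropped for
identifiability), screened covariates and the single term; testing one
pair at a time with full main effects keeps each fit well-conditioned at
realistic carrier counts, at the price of mild misspecification when
several interactions are real. Multiplicity default is Bonferroni over
the tested pairs.

**Tag selection.** Per kept haplotype the candidate maximizing phased
r² wins; ties break by |D′| then genomic position, and a best candidate
below `min_r2` (default 0.7 — an artifact default, exposed in the
interface) yields an explicit "untagged" row. D′ follows Lewontin's
formulation with $D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D>0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ for $D<0$, and D′ = 0 at D = 0. When no
phased data are available, LD falls back to squared Pearson correlation
of dosages, flagged `method = "dosage"` (D′ is then unavailable).

**Discrimination.** AUC is the Mann-Whitney concordance probability with
ties counted ½, so it is invariant under strictly monotone transforms
and equals exhaustive pair counting (asserted in the tests). PRAUC uses
average precision — step-wise integration over recall increments —
because trapezoidal interpolation systematically overestimates PR
curves. DeLong variances come from structural components, with a normal
approximation for both the paired and unpaired designs and no
small-sample correction (intended n ≥ 100; note pROC's unpaired variant
uses a t-tail, so its p differs slightly from ours at small n while the
statistic agrees). Thresholds are applied as "score > t calls a case",
and centile cutoffs/tertiles use type-7 quantiles — stated explicitly
because centile-based cutoffs are sensitive to the quantile convention.
The dual-direction rule (`direction = "less"`) supports a low cutoff
calling the other class with fixed specificity.

## What the validation shows — and does not

The test suite and `scripts/acceptance.R` validate the machinery by
parameter recovery and calibration, at problem sizes chosen to estimate
each quantity precisely without waste:

* published SNP β recovery: 200 replicate cohorts of 1300/2200 per
  marker, mean $\hat\beta$ within 3 Monte-Carlo SE of the printed value;
* type-I error of the Wald SNP test (2000 null SNPs at n = 3000), the
  interaction test (1000 simulated null cohorts) and the paired DeLong
  test (1000 replicates), each required to land in [0.035, 0.065] at
  α = 0.05;
* planted tags at r² targets {1.0, 0.9, 0.8} recovered within 3 SE on
  10⁵ chromosomes, with the SE measured by replicate re-emission (the
  realized r² of a planted tag has sampling noise dominated by the flip
  draws, which a normal-theory correlation SE badly underestimates);
* exact agreement of AUC, HWE and LD computations with brute-force
  oracles;
* an end-to-end pipeline run (3000 individuals) in which the combined
  score's AUC exceeds that of every component.

Because the simulator generates exactly the structures the estimators
assume — i.i.d. haplotypes, binomial dosages in linkage equilibrium,
logistic penetrance, uniform missingness — passing these tests shows the
estimators are *correct*, not that the score will transfer to real data.
Real cohorts add population structure beyond supplied PCs, background LD
between "independent" SNPs, typing and imputation error in the HLA
region, informative missingness, and genuine model misspecification; none
of these are emulated. The recovery studies use single-SNP cohorts with
no missingness: marginal logistic slopes are attenuated by omitted
independent risk factors (non-collapsibility) and by mean imputation, so
a multi-signal cohort would *not* be expected to return the printed βs
exactly — that is a property of logistic regression, not an estimator
defect.

Known limitations: two-locus phasing only (no multi-locus EM, no
DRB1/DPB1); no recombination or background LD in the simulator; Wald
rather than likelihood-ratio inference everywhere; fixed-effect
meta-analysis only; interaction power depends on carrier counts, so
modest planted effects routinely fail Bonferroni at n ≈ 3000 (visible in
the README example) without indicating any defect.
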