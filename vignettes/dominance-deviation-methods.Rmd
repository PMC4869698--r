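---
title: "Testing deviation from additivity: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing deviation from additivity: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

GWAS practice usually assumes a per-allele additive model: with $g \in \{0,1,2\}$
copies of an effect allele, the heterozygote mean lies exactly halfway between
the two homozygote means. `domdev` tests departures from that assumption with
the *dominance deviation* model,

$$ y = \beta_0 + \beta_A\, g + \beta_D\, h + \gamma' c + \varepsilon, $$

where $h$ is the heterozygote indicator (coded 0/1/0) and $c$ are covariates.
Under additivity $\beta_D = 0$; a purely recessive effect of size $\delta$
implies $\beta_A = \delta/2$ and $\beta_D = -\delta/2$, i.e.
$\beta_D = -\beta_A$; a purely dominant effect implies $\beta_D = +\beta_A$.
The same coding carries over to logistic regression for binary traits, where
$\exp(\beta)$ is an odds ratio and "additive" means multiplicative per allele:
the expected homozygote OR is the square of the heterozygote OR
(`expected_hom_or_under_additive()`), and conversely
(`expected_het_or_under_additive()`).

Additive p values are reported from the additive-only fit and
dominance-deviation p values from the joint (genotypic) fit; on hard calls the
joint fit is the saturated three-class model, so
$\hat\beta_0 = m_0$, $\hat\beta_A = (m_2 - m_0)/2$,
$\hat\beta_D = m_1 - (m_0 + m_2)/2$ exactly — an identity the tests exploit
against an individual-level OLS oracle.

P values are two-sided Wald throughout (normal reference above n = 1000, t
below), matching standard GWAS output. Logistic fits use IRLS
(`stats::glm.fit`, relative tolerance $10^{-10}$, 50 iterations); complete
separation is flagged (any $|\hat\beta| > 15$ or non-convergence) rather than
raised as an error, since a genome-wide scan must keep going.

## Genotype uncertainty

Imputed genotypes enter the regression either as maximum-probability hard
calls or as expectations: $g =$ dosage and $h = P(\mathrm{het})$, the
expectation of the 0/1/0 code. Defaults follow use: the scan's regression
terms use dosages, genotype-class summary tables use hard calls (class tables
are inherently discrete). Hard-call ties break toward fewer alternate
alleles — deterministic and conservative for rare alleles.

## Variant QC

Variants are excluded when imputation info < 0.9, Hardy–Weinberg exact-test
p < 1e-6, or MAF < 0.5%. All boundaries are strict exclusions, so a value
exactly at the threshold passes; this is the only reading consistent with
describing the filters with "<". The HWE test is the conditional exact test on
hard-call counts (Wigginton et al. 2005), computed in log space over all
heterozygote counts compatible with the allele counts; the chi-square
goodness-of-fit test is retained in the test-suite as an independent oracle
(the two agree within 0.3 log10 units whenever expected class counts exceed
5). Failed criteria are all recorded, not just the first, so QC reports
reconcile exactly.

Independent-variant counting uses greedy pruning in position order with a
sliding window (1000 variants / 1 Mb) and an r² threshold of 0.9; the window
and greedy rule are the package's own choices, as only the threshold is
standard. D′ is estimated from the phase-free composite (Burrows)
disequilibrium and reported descriptively only — it is exactly 1 for
self-comparison only at perfect HWE proportions, which is why no filter uses
it.

## Phenotype preparation

Two BMI measures (weight/height² and impedance-derived) are reconciled by
excluding samples whose difference exceeds 4.56 SDs of the difference vector.
The SD is computed in a single pass over all samples with both measures,
before any exclusion: the constant is fixed, the reference population is not,
and the single-pass reading is the simplest faithful one (iterating to a
fixed point would change the excluded set only in pathological cases).

BMI is residualised on age, sex, centre and five principal components by OLS,
then rank inverse-normalised with Blom offsets
($\Phi^{-1}((r - 3/8)/(n + 1/4))$, configurable), with average ranks on ties
so the phenotype path needs no seed. The transform is idempotent up to ties
and invariant under monotone transforms of its input.

Case definitions: obese = BMI > 30, severely obese = BMI > 40, controls < 25,
the bands between excluded, all strict. Type 2 diabetes cases require a
self-report of type 2 or generic diabetes, no insulin within the first year,
a known diagnosis age of at least 35 (exactly 35 is eligible: the exclusion
is "under 35"), and diagnosis more than one year before data extraction
(`study_end_window_years`, default 1, models an extraction date that is not
otherwise observable). Type 1 self-reports are excluded; non-reporters are
controls. Every sample lands in exactly one of case/control/excluded, with a
reason code.

## The synthetic cohort

No individual-level biobank data can ship with a package, so the generator
produces cohorts with the structure the analysis assumes, and the defaults
*are* the stated world of the study the pipeline emulates:

- `n_samples` defaults to 120,286 (the analysis cohort size); tests scale
  down and say so.
- Hard genotypes are drawn from HWE proportions $p^2, 2pq, q^2$ at a
  frequency drawn from `maf_range`; imputation noise mixes each one-hot
  genotype with the population HWE vector using weight $w = 1-\sqrt{s}$,
  which scales the dosage SD by $\sqrt{s}$ about an unbiased mean so the
  realised info statistic $\mathrm{var}(\mathrm{dosage})/2pq$ approximates
  the target $s$ (and is exactly 1 when $s = 1$).
- BMI residuals are exponentiated-normal: a standardised
  $\exp(\text{skew}\cdot Z)$, right-skewed like real BMI. The default skew
  0.17 gives a skewness of ~0.5, of the order seen in adult BMI; skew 0
  recovers Gaussian noise. Baseline mean 27.5 and SD 4.8 kg/m² match the
  class-table grand mean and pooled SD.
- The impedance BMI is the standard measure plus noise (SD 0.5 kg/m²), with
  a gross ±8–12-noise-SD offset at `discordance_rate` (default 0.001). The
  published cohort's true impedance computation is not described anywhere
  usable, so this emulates only what the exclusion rule needs: occasional
  gross discordance on a background of agreement.
- Type 2 diabetes status is logistic in age, sex and planted liability
  effects at a base prevalence of 3.5% (≈ 4,040/117,775); questionnaire
  fields are populated so that 5% of reporters violate each exclusion rule
  (type 1 label, first-year insulin, diagnosis under 35, recent diagnosis,
  unknown age) — values the study does not state, chosen once so every
  downstream rule is exercised at realistic but non-negligible rates.
- One global seed expands into per-stage substreams, so genotype and
  phenotype stages are individually reproducible and the whole run is
  byte-identical under a fixed config.

What the generator does **not** emulate: linkage disequilibrium between
variants (beyond test-constructed copies), relatedness, haplotype structure,
genotyping batch artefacts, or the real shape of questionnaire missingness.
A green pipeline test therefore establishes correctness of the statistical
machinery on data satisfying its assumptions — not robustness to the
confounders that motivate PCs and kinship pruning in real cohorts, which are
consumed here as plain covariate columns by design.

## Grouped statistics from printed tables

Class-summary triplets (n, mean, SD) are sufficient statistics for any
regression on genotype class: weighted least squares on the class means with
weights n equals individual-level OLS on class-constant data to machine
precision (tested at 1e-10). Sums of squares decompose as
total = within + between with within $= \sum (n_g-1)\,\mathrm{SD}_g^2$; the
genotypic-over-additive R² increment is reported in percent. On the shipped
FTO class table the increment computes to ≈ 0.017% where the source printed
0.01%: with means given to 2 dp the last digit of a ~0.015% quantity is not
recoverable, so the acceptance band is |x − 0.015| ≤ 0.01 percentage points
and the point value is not asserted.

Odds ratios use the cross-product with Woolf log-SE
$\sqrt{1/a+1/b+1/c+1/d}$ and a flagged Haldane–Anscombe 0.5 correction on
zero cells.

## Meta-analysis, thresholds, power

Fixed-effects combination is inverse-variance on a common effect scale. When
a study supplies several of SE / CI / p, recovery precedence is SE > CI > p:
an explicit SE is the author's own number, a CI reproduces it to rounding,
and a p value degrades it most (for the shipped replication study the CI
gives 0.00587 where the p value implies 0.00640 — materially different
weights). Combining the discovery cohort (β = −0.025, SE = 0.006) with the
replication consortium (β = −0.019, CI-derived SE) yields p ≈ 1.7 × 10⁻⁷;
the source prints 1 × 10⁻⁷ from unrounded inputs, so the test asserts the
order of magnitude (p < 10⁻⁶) only. Reported total n is the sum of the
inputs (225,331); the source's 225,143 evidently reflects per-variant
missingness we cannot see.

Bonferroni thresholds are α/m with a one-significant-figure rendering
(round-half-away-from-zero on the mantissa): 0.05/15,005,727 → "3 x 10^-9",
0.05/72 → "7 x 10^-4", 0.05/66 → "8 x 10^-4".

Power of the 1-df Wald/score test uses the non-central chi-square with
NCP = n·r², the same formulation QUANTO uses for a variance-explained
parameterisation: at n = 119,688, r² = 0.0004, α = 3 × 10⁻⁹ the power is
0.838. A purely recessive shift of `effect` units at allele frequency q
explains $\mathrm{effect}^2 q^2(1-q^2)/\sigma^2$ of variance — 0.04% for
0.4 kg/m² at q = 0.25 against the pooled class-table SD (4.82 kg/m²).
Case-control designs are compared through the effective sample size
$4/(1/N_\mathrm{cases} + 1/N_\mathrm{controls})$.

## Report rendering

Genotype-class CI bounds are truncated toward zero at 2 dp (means rounded):
mean 27.27 with CI (27.2257, 27.3143) prints as "27.27 (27.22, 27.31)". This
is the convention that reproduces the reference table's first row exactly;
its other rows were evidently printed from unrounded means and match no
convention applied to the rounded inputs, so exactness is only claimed where
the inputs permit it.

## Known limitations

- The scan loops variants in R; at desk scale (thousands of variants) this
  is seconds, but it is not a biobank-scale engine and does not try to be.
- `read_vcf()` parses the package's own GT/DS dialect (checked against
  VariantAnnotation in the tests); it is not a general VCF reader — no
  multi-allelic splitting, no BGEN/PGEN.
- Dominance-deviation power falls steeply with MAF (the heterozygote-excess
  contrast has variance ~2pq(1−2pq)); nothing in the package corrects for
  that — it is the reason genome-wide dominance scans are underpowered for
  rare alleles.
- The composite D′ estimator is biased upward in small samples and is
  deliberately excluded from any filtering decision.
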