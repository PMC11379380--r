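---
title: "Methods: reverse dosimetry and Monte-Carlo risk assessment for 2-OHNAP biomonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse dosimetry and Monte-Carlo risk assessment for 2-OHNAP biomonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naphrisk)
```

## Scope and model

`naphrisk` implements a biomarker-based ("internal dose") risk assessment
for naphthalene: urinary 2-hydroxynaphthalene (2-OHNAP) concentrations are
converted to an estimated daily intake (EDI) of the parent compound by
reverse dosimetry, and population variability is propagated through the
hazard-quotient (HQ) and carcinogenic-risk (CR) formulas by Monte-Carlo
simulation. The approach assumes steady-state excretion (a day's urinary
metabolite output reflects a day's intake), complete conversion accounting
via a single excretion fraction `f`, and dietary intake as the dominant
exposure route for non-smokers.

Two EDI routes are first-class. The *original* route uses the uncorrected
urinary concentration and divides by the individual's body weight:

$$\mathrm{EDI_O} = \frac{C_u \, V_u \, (MW_p / MW_m)}{f \, BW}.$$

The *creatinine* route uses the dilution-corrected concentration
(µg analyte per g creatinine) and replaces the urine-volume/body-weight pair
with the physiological daily creatinine excretion rate $C_c$
(mg creatinine/kg-bw/day):

$$\mathrm{EDI_C} = \frac{C_s \, C_c \, (MW_p / MW_m)}{f \cdot 1000},$$

where the 1000 converts $C_c$'s milligrams of creatinine to grams,
cancelling $C_s$'s per-gram basis. When an individual's
$C_c \cdot BW$ equals their actual daily creatinine mass
($\mathrm{creat}_{g/L} \cdot V_u \cdot 1000$), the two routes coincide
exactly — an algebraic identity the test suite exercises with random
inputs.

Risk indices: $HQ = \mathrm{EDI}/\mathrm{RfD}$ and
$CR = (\mathrm{EDI} \cdot 10^{-3}) \cdot \mathrm{TEF} \cdot \mathrm{CSF}$,
with the benzo[a]pyrene-equivalent intermediate
$\mathrm{EDI_{BaPeq}} = \mathrm{TEF} \cdot \mathrm{EDI}$ (mg/kg-bw/day)
exposed via `bap_equivalent()`. For any shared EDI the two indices are
proportional: $CR = HQ \cdot \mathrm{RfD} \cdot 10^{-3} \cdot \mathrm{TEF}
\cdot \mathrm{CSF} = HQ \cdot 1.46\times10^{-4}$ at the default parameters.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `v_u` | 2 | L/day | daily urine volume |
| `f` | 1 | – | urinary excretion fraction of 2-OHNAP |
| `mw_parent` / `mw_metabolite` | 128.17 / 144.17 | g/mol | naphthalene / 2-OHNAP |
| `cc_male`, `cc_female` | 23, 18 | mg/kg-bw/day | daily creatinine excretion |
| `rfd` | 20 | µg/kg-bw/day | naphthalene oral reference dose |
| `tef` | 0.001 | – | potency relative to benzo[a]pyrene |
| `csf` | 7.3 | (mg/kg-bw/day)⁻¹ | B[a]P oral cancer slope factor |

The molecular-weight ratio is oriented by mole conservation: one mole of
excreted metabolite implies one mole of absorbed parent, so parent mass =
metabolite mass × 128.17/144.17 ≈ 0.889 (< 1). Source tabulations of this
model sometimes swap the symbol labels; both weights are plain arguments of
`exposure_params()`, so the inverted convention is reproducible if a
comparison requires it. The CSF of 7.3 is the standard benzo[a]pyrene oral
slope factor. EDI is carried in µg/kg-bw/day everywhere; the µg→mg
conversion happens once, inside `cancer_risk()`, which eliminates a whole
class of 10³ bookkeeping errors.

## Monte-Carlo engine

`run_mcs()` draws `n_iterations` independent (concentration, body-weight)
pairs and maps each through the selected route. Concentration is lognormal,
*moment-matched*: given an arithmetic mean $m$ and SD $s$,
$\sigma^2 = \ln(1 + (s/m)^2)$ and $\mu = \ln m - \sigma^2/2$, so the
simulated arithmetic moments equal the published ones. Body weight is
normal truncated below at 30 kg (rejection sampling). Uncertainty is placed
on concentration and body weight only; `v_u`, `f`, `C_c`, RfD, TEF and CSF
are point constants, since only point values are available for them and the
originating workflow names no distributions for its stochastic inputs —
the lognormal choice here is this package's own, motivated by positivity
and the strong right skew of the published summaries (mean 20.38 ≫ median
7.6 µg/L). Results are therefore distribution-assumption-sensitive at
roughly the factor-of-1.5 level on the mean CR, which is the tolerance the
acceptance checks use.

Summaries report P5 / mean / P95 (percentiles by linear interpolation
between order statistics, `quantile(type = 7)` — the spreadsheet
convention) and exceedance fractions with *strict* inequality (ties have
probability zero for continuous draws): HQ at 0.1 and 1, CR at 10⁻⁶ and
10⁻⁴.

Stratification: the original route always draws the pooled uncorrected
concentration (gender-resolved uncorrected summaries are not published) and
varies the body-weight distribution by stratum. The creatinine route draws
the gender-specific corrected concentration for the male/female strata; the
"all" stratum draws the pooled corrected distribution and splits iterations
equally between the male and female $C_c$ — an equal-weight mixture
matching the 25/25 design.

A note on reproducing published endpoints: with 10⁵ moment-matched
lognormal draws the simulated CR maximum slightly exceeds 10⁻⁴ (the
lognormal right tail is long); the mean CR and the exceedance fractions are
the robust, reproducible summaries and are the only ones the package's
checks assert.

## The synthetic cohort generator

No per-subject data are published, so `generate_cohort()` emulates the
printed cohort structure: 50 polluted-area residents (25 male / 25 female),
ages truncated-normal on the recruitment range [18, 70] (46.62 ± 12.87),
BMI 25.16 ± 4.2, gender-specific body weights (71.4 ± 14.2 / 62.8 ± 8.4 kg,
truncated at 30 kg), plus 4 controls. Concentrations are lognormal,
moment-matched; urine draws are truncated above the LOD (0.2 µg/L — the
untruncated mass below it is ~10⁻⁵), reproducing the 100% urine detection
rate. Hair non-detects are a *fixed count* — `round(0.12 × n) = 6`,
assigned to the lowest-ranked draws — rather than Bernoulli censoring at
the LOD, because a lognormal matched to the printed hair moments
(8.16 ± 7.62 ng/g) puts essentially no mass below 0.2 ng/g; the fixed count
reproduces the printed 88% detection rate exactly and keeps tests
deterministic.

Two published urinary scales must be reconciled: the uncorrected mean
(20.38 µg/L) and the creatinine-corrected mean (16.65 µg/g creatinine),
with a printed creatinine mean of 144.326 mg/dL but no creatinine SD. The
generator draws the *uncorrected* concentration as primary (it is what the
original-route risk engine consumes) and derives the corrected value as
$C_u / \mathrm{creat}_{g/L}$ with creatinine drawn lognormally,
independently of $C_u$. Under independence
$E[C_s] = E[C_u] \cdot E[1/\mathrm{creat}]$, and
$E[1/\mathrm{creat}]$ grows with the creatinine CV; the default CV of 0.423
(SD 61.1 mg/dL) is the unique value at which both printed means hold in
expectation. That CV is well inside the physiological range for spot-urine
creatinine. Urine and hair are drawn independently within participant,
consistent with the published near-zero hair–urine rank correlation; both
genders share one concentration distribution, consistent with the published
non-significant gender differences. Each variable block derives its own
RNG stream from the root seed, so resizing the control group does not
perturb the polluted-group draws.

What the generator does **not** emulate: within-subject correlation between
creatinine and analyte concentration (real spot urines correlate both with
hydration), diet and lifestyle covariates, measurement error, or the exact
published extremes. Passing calibration tests therefore shows the pipeline
is faithful to the published *summary structure*, not that it would
reproduce per-subject inferences on the real data — in particular the
published per-day gender EDI means and the exact hair–urine correlation
depend on unpublished per-subject values and are deliberately not targeted.

## Censoring and normalisation

Non-detects are substituted by LOD/2 (LOD 0.2 µg/L urine, 0.2 ng/g hair)
for risk and statistics. The raw value is never overwritten: the
substitution lands in a `working_value` column, keeping the rule auditable
and idempotent. Values between LOD and LOQ (1.17) are treated as valid
detects and flagged `below_loq` for reporting. The fixed operation order is
substitute-then-correct; it matters only when urine non-detects exist,
which the study emulation never produces. No censored-likelihood fitting is
attempted (out of scope by design).

## Statistics layer

`describe_values()` uses the n−1 sample SD and middle-order-statistic
medians. Rank procedures: `mann_whitney_u()` reports U = min(U₁, U₂) with
an exact p when the pooled sample is ≤ 12 and tie-free, else a
tie-corrected normal approximation (no continuity correction — at extreme
group-size imbalance, e.g. 50 vs 4, the continuity-corrected p cannot fall
below ~10⁻³ even for complete separation, understating the evidence);
`kruskal_wallis()` is the tie-corrected H with a χ² p; `spearman_rho()`
uses average ranks, exact permutation enumeration for n ≤ 8 and the t
approximation with n−2 df otherwise. Normality screening is
Kolmogorov-Smirnov with the Lilliefors correction (via `nortest`), because
the naive KS p is anticonservative when the reference normal's parameters
are estimated from the sample; the parametric t/ANOVA branch such screening
would enable is available in base R and intentionally not wrapped, since
right-skewed biomarker data essentially never pass the screen. All p-values
are two-sided; no multiple-testing correction is applied (matching the
workflow being emulated, which applies none).

## Numerical and degenerate-input choices

* `sd = 0` distribution specifications degenerate to point masses, which
  makes the whole simulation collapse to the closed-form point calculation
  — the strongest available engine oracle, asserted to machine precision.
* Rejection sampling for truncated draws is exact (no importance weights);
  acceptance rates at the defaults are ≥ 99% for body weight and ≈ 97% for
  age.
* Constant vectors raise explicit degenerate-input errors in the
  correlation, H and KS procedures rather than returning NaN.
* Exceedance uses strict `>`; percentile type 7 ties the reporting to the
  spreadsheet lineage of this workflow.
* All randomness flows from user-visible integer seeds; `run_mcs()` and
  `generate_cohort()` restore the caller's RNG state.

## Problem sizes

The shipped configuration runs 10⁵ Monte-Carlo iterations per simulation
cell (about a second each); the test suite uses 10³–2×10⁴ iterations for
engine contracts, 10⁵ where a published quantity is checked, and
1000-replicate null simulations for the type-I-error properties — sizes
chosen so the whole suite runs in well under a minute while keeping
binomial noise on rejection rates (±0.7 percentage points) far inside the
asserted [0.03, 0.07] band.

## Known limitations

* Single-metabolite, single-route: no multi-PAH mixture or cumulative risk,
  no inhalation/dermal apportionment, no lifetime/age-segmented adjustment.
* The reverse-dosimetry constants (`v_u`, `f`, `C_c`) are population point
  values; individual physiology varies around them and that variance is not
  propagated.
* Lognormality of concentrations is an assumption, not an observation;
  alternative right-skewed families (gamma, Weibull) would shift tail
  quantities like the CR maximum more than the mean.
* The synthetic cohort reconciles published summaries that are not mutually
  consistent under independence (uncorrected mean × mean creatinine ≠
  corrected mean); the chosen creatinine CV resolves the means but the
  corrected-scale SD is then a consequence, not a calibrated target.
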