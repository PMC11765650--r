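---
title: "Screening condylar hyperplasia with craniofacial fluctuating-asymmetry indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening condylar hyperplasia with craniofacial fluctuating-asymmetry indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymscreen)
```

## The problem

Unilateral condylar hyperplasia (CH) is a non-neoplastic overgrowth of one
mandibular condyle that drives a vertical-vector facial asymmetry;
hemimandibular elongation (HE) produces a horizontal-vector asymmetry without
condylar overgrowth. Both displace anatomical landmarks that surgeons use as
reference points, most visibly the three facial foramina through which the
trigeminal branches exit: the supraorbital (SOF), infraorbital (IOF) and
mental (MFO) foramen. Measuring the vertical distances between these foramina
on each side of the face — SOF–IOF, IOF–MFO, SOF–MFO, right and left — and
the three horizontal left-to-right distances (SOF–SOF, IOF–IOF, MFO–MFO)
gives a compact morphometric summary of how a pathology distorts the facial
skeleton. All distances in this package are lengths in centimetres.

`asymscreen` implements the full analysis such a measurement design supports:
per-subject fluctuating-asymmetry indices, rank-based comparisons between
sexes and between diagnostic groups (CONTROL / HE / CH), and an evaluation of
the indices as screening predictors of CH via ROC and cutpoint analysis.

## Fluctuating-asymmetry indices

For a bilaterally paired trait with right and left measurements $R$ and $L$,
the package computes the two classical Palmer-style indices

$$\mathrm{FA1} = |R - L|, \qquad
  \mathrm{FA2} = \frac{|R - L|}{(R + L)/2}.$$

FA1 keeps the units of the measurement; FA2 divides by the bilateral mean,
making the index dimensionless and invariant to a common rescaling of both
sides, so it corrects for between-individual size differences. For positive
sides FA2 lies in $[0, 2)$. The composite predictors Total FA1 and Total FA2
are the sums of the respective index over the three paired vertical traits —
summation is deliberate: each trait contributes independent evidence of
asymmetry, and adding them amplifies a pathology that disturbs all three.
The horizontal distances have no left/right pairing and therefore no FA
index; they enter only the descriptive and between-group tables.

A subject missing one side of a paired trait contributes nothing to that
trait's indices; the composite is then the sum over the traits that remain,
with `traits_used`/`n_traits_used` recording how many entered. A subject with
no computable paired trait is an error in strict mode and an all-`NA` row
otherwise.

## Statistical comparisons

Craniofacial distances in small clinical series are rarely normal, so all
comparisons are rank-based:

* **Sexes** are compared per variable with the Mann–Whitney U test. The
  p-value is exact when both samples have at most 8 observations and no ties;
  otherwise the tie-corrected normal approximation with continuity correction
  is used, the regime that mainstream software applies at the 15-versus-15
  sample sizes typical of this design.
* **Diagnostic groups** are compared with the tie-corrected Kruskal–Wallis
  test on $k - 1 = 2$ degrees of freedom, followed by all-pairs post-hoc
  comparisons. The default post-hoc method is
  Dwass–Steel–Critchlow–Fligner (DSCF), which re-ranks each pair jointly and
  refers the standardised rank-sum statistic to the Studentized range with
  $k$ means — the Kruskal–Wallis post-hoc that mainstream statistics GUIs
  run by default. Dunn's test with Holm adjustment is available via
  `posthoc = "dunn"` for users who prefer the joint-ranking convention. For
  two groups DSCF collapses to the tie-corrected normal Mann–Whitney test,
  which the test suite exploits as an exactness check.

The significance threshold is $\alpha = 0.05$, applied inclusively
(p = 0.05 is flagged) in all rendered tables. No multiple-testing correction
is applied across the 15 report variables; the tables flag raw p-values, and
readers who need family-wise control can apply it downstream.

Fully degenerate inputs are defined rather than thrown: identical values in
every group give $H = 0$, $p = 1$; a single-observation stratum reports
SD 0 with a degeneracy flag (or an error in strict mode).

## ROC screening engine

The screening question is asymmetric: CH is the condition worth catching
early, so CH is the positive class and HE and controls together are the
negatives. Larger FA indices indicate CH, hence the classification rule is
*score ≥ cutpoint → positive*.

The ROC engine is exact and empirical: thresholds are the sorted unique
observed scores plus a $+\infty$ sentinel, so the curve always contains both
endpoints. The AUC uses the Mann–Whitney pair-counting form — the fraction of
(positive, negative) pairs in which the positive subject scores higher, ties
counted half — which equals the trapezoidal area under the empirical step
curve exactly; the test suite verifies the equality to $10^{-12}$ and checks
the implementation against an independent ROC library.

`optimal_cutpoint()` scans the observed score values and maximises Youden's
index $J = \text{sensitivity} + \text{specificity} - 1$. Scanning observed
values rather than midpoints loses nothing: under a "≥" rule any cutpoint
between two adjacent observed values classifies identically to the next
observed value, a fact the oracle tests confirm by scanning midpoints too.
Ties in $J$ are broken towards higher sensitivity and then towards the lower
cutpoint — a screening-oriented convention: an initial screen should prefer
catching true cases over avoiding false alarms. Reported metrics are
sensitivity, specificity, PPV, NPV (both prevalence-dependent, computed from
the in-sample confusion matrix), Youden's index and AUC. Confidence
intervals are not reported; the evaluation is in-sample by design, matching
how preliminary clinical series report these quantities, and no
cross-validation or smoothed ROC is attempted.

## The synthetic-cohort generator

Clinical CBCT measurements of this kind are not publicly deposited, so the
package ships a generator that emulates the statistical structure the
analysis assumes, making every stage testable end-to-end. The model, per
subject:

1. a size factor $s \sim N(1, \text{cv})$ scales all trait baselines
   (default cv 0.05), creating the between-individual size variation FA2 is
   meant to remove;
2. each paired trait gets a signed asymmetry deviate
   $d \sim N(0, \sigma_{\text{trait, group}})$ split evenly between sides:
   $R = b + \delta/2 + d/2 + \varepsilon_R$,
   $L = b - \delta/2 - d/2 + \varepsilon_L$, with directional offset
   $\delta$ (default 0: pure fluctuating asymmetry) and independent per-side
   measurement noise $\varepsilon \sim N(0, 0.03\ \text{cm})$;
3. horizontal traits are $b + \varepsilon$;
4. non-positive draws are rejected and redrawn.

With measurement noise off, FA1 of a trait is exactly half-normal with scale
$\sigma$, so its population mean is $\sigma\sqrt{2/\pi}$ — the closed form
the calibration and the tests lean on.

**Calibration.** Per-sex baselines are the observed right-side sex means of a
30-subject clinical CBCT series (e.g. female SOF–MFO 10.59 cm, male 11.36 cm;
female IOF–IOF 5.21 cm, male 5.56 cm). Control asymmetry scales are derived
by inverting the half-normal identity from that series' pooled FA1 means,
giving $\sigma_{\text{control}} \approx$ 0.17 (SOF–IOF), 0.50 (IOF–MFO) and
0.63 cm (SOF–MFO). Group effects follow the qualitative structure such
cohorts show: CH at 5× the control scale on every paired trait, HE equal to
control except SOF–MFO at 2×. The 5× ratio is a deliberate default chosen so
that the composite predictor clears AUC 0.9 — for a single trait with scale
ratio $\rho$ between half-normal classes the AUC is
$\tfrac{2}{\pi}\arctan\rho \approx 0.874$ at $\rho = 5$, and summing three
independent traits strictly improves on it — and it is an ordinary config
knob, not a constant. Sex offsets apply to baselines only, never to the FA
scales: sexes differ in size, not in asymmetry, and the generator preserves
that.

**Determinism.** Each subject draws from an RNG stream seeded by a
deterministic function of the root seed and the subject's position in the
fixed (group, sex, replicate) enumeration, so a cohort is byte-identical
across runs and robust to reordering of generation.

**What the generator does not emulate.** Real CBCT series carry heavy-tailed
measurement errors, landmark-identification bias, correlated asymmetry across
traits (all three vertical distances share the mental foramen, so their
deviates are not independent in reality), age structure, and
directional asymmetry of the population. Passing tests on synthetic cohorts
therefore demonstrate that the *procedure* is implemented correctly and is
well-calibrated under its stated model — not that the published effect sizes
generalise to new patients.

## Numerical and design choices

* Default cohort shape is 3 groups × 2 sexes × 5 subjects (30 total, 10 per
  group, sex-balanced), the design of the reference series.
* CSV is the interchange format (fixed header, empty cell = missing, UTF-8);
  measurements survive a write/read round trip bit-for-bit.
* Cutpoint ties are resolved deterministically (Youden, then sensitivity,
  then lower cutpoint) so reports are reproducible.
* Problem sizes used by the validation suite were chosen for statistical
  resolution: the half-normal calibration check uses 1,200 subjects (mean
  within 3 standard errors), the null-calibration check uses 1,000 replicate
  30-subject cohorts (type-I error within [0.03, 0.07] at α = 0.05), and the
  composite-AUC check uses 100 replicates of 100 CH + 100 control subjects.
* Values and composites are computed in double precision with no rounding
  until rendering; rendered tables round means to 4 decimals, χ² to 3 and
  percentages to 2.

## Limitations

The screening evaluation is in-sample on small cohorts, so reported
sensitivities and predictive values are optimistic; PPV/NPV are tied to the
1:2 positive:negative mix of the design and do not transfer to populations
with a different CH prevalence. The group-level asymmetry scales of real CH
and HE populations are unknown — the generator's defaults are explicitly
synthetic — and the indices deliberately ignore directional asymmetry and
antisymmetry, which a full Palmer-style decomposition would examine before
attributing all side differences to developmental instability.
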