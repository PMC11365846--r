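---
title: "Methods: water quality indices and probabilistic exposure in aquarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water quality indices and probabilistic exposure in aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

aquarisk screens groundwater chemistry and quantifies the health and
ecological risks of four potentially toxic elements (PTEs: Fe, Mn, Cu, Zn)
in drinking water. This vignette explains the models, the conventions and
numerical choices behind them, what the synthetic cohort generator does and
does not emulate, and the package's known limitations. Nothing stated here
as an empirical result goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Hydrochemical screening

All ion arithmetic happens in milliequivalents per litre, using a pinned
table of equivalent weights (g/eq): Ca 20.04, Mg 12.15, Na 22.99, K 39.10,
Cl 35.45, SO4 48.03, HCO3 61.02, CO3 30.00, NO3 62.00. Pinning the table
(rather than recomputing from atomic masses at run time) makes every meq
result bit-reproducible. NO3 is treated as monovalent.

**Charge balance.** `charge_balance_error()` computes
$\mathrm{CBE} = 100\,(\Sigma\mathrm{cat} - \Sigma\mathrm{an})/(\Sigma\mathrm{cat} + \Sigma\mathrm{an})$;
$|\mathrm{CBE}| \le 5\%$ marks a chemically credible analysis. This is the
QA gate every laboratory cohort must pass, and the synthetic generator
enforces it on its output.

**Chloro-alkaline indices.** CAI-I $= [\mathrm{Cl} - (\mathrm{Na}+\mathrm{K})]/\mathrm{Cl}$
and CAI-II with the denominator $\mathrm{SO_4}+\mathrm{HCO_3}+\mathrm{CO_3}+\mathrm{NO_3}$,
all meq/L. Negative values indicate direct ion exchange (aquifer Na/K
released to the water, dissolved Ca/Mg sorbed). The Schoeller numerator is
the default; a `cai_numerator = "as_printed"` switch reproduces a variant
numerator $\mathrm{Cl} - (\mathrm{Na}-\mathrm{Ca})$ that circulates in the
applied literature (almost certainly a typographic slip of the Schoeller
form, kept for comparability). Because both CAI denominators are positive,
the two indices always share a sign; the tests assert this.

**Facies, Gibbs and Sulin classifiers.** These diagrams are usually read by
eye; aquarisk fixes explicit numeric rules so the labels are reproducible:

* *Piper facies*: cation side is alkali-dominated when Na+K > 66 meq%,
  alkaline-earth-dominated when Ca+Mg > 66%, otherwise mixed; anion side
  has single-ion dominance at > 50% (HCO3 grouped with CO3) and a grouped
  Cl/SO4 class at a combined > 66%. The 66% cation threshold (rather than
  50%) is what makes a 55% Na / 35% Ca water a *mixed* Na–Ca type, matching
  how mixed facies are reported in practice. Combinations outside the five
  named facies, and exact threshold ties, return `"other"`.
* *Gibbs mechanism zones* are the classical boomerang digitized to
  rectangles in (TDS, Na/(Na+Ca)) space: rock-weathering at TDS
  70–1000 mg/L and ratio < 0.75; evaporation/crystallization at TDS > 1000
  and ratio > 0.5; precipitation at TDS < 70 and ratio > 0.5. Points
  outside every box attach to the nearest zone centre (TDS on a log scale).
* *Sulin origin*: r(Na)/r(Cl) > 1 splits into Na2SO4 (deep meteoric) when
  (rNa−rCl)/rSO4 > 1 and NaHCO3 (shallow meteoric) otherwise;
  r(Na)/r(Cl) < 1 splits into MgCl2 (old marine) when (rCl−rNa)/rMg < 1
  and CaCl2 (recent marine) otherwise.

**Laboratory QA.** `qa_stats()` implements LOD = 3·SD(blank),
LOQ = 10·SD(blank) (so LOQ/LOD = 10/3 exactly) and %RSD with the sample
(n−1) standard deviation — appropriate for triplicate readings.

## The integrated-weight water quality index

The index combines two *objective* weighting schemes computed from the
cohort's own data matrix (m samples × n parameters, default the 14
parameters TDS, pH, EC, Na, K, Mg, Ca, Mn, Fe, Cl, SO4, HCO3, NO3, TH):

1. **Normalization**: $Y_{ij} = (X_{ij} - \min_j)/(\max_j - \min_j)$.
   A constant column is set to all zeros with a warning.
2. **Entropy weights** $w^1_j$: $P_{ij} = Y_{ij}/\sum_i Y_{ij}$,
   $e_j = -\tfrac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}$ (with
   $0\ln 0 := 0$), $w^1_j = (1-e_j)/\sum_j (1-e_j)$. A degenerate column
   gets $e_j = 1$ (zero information) and weight 0.
3. **CRITIC weights** $w^2_j$: $S_j = \delta_j \sum_k (1 - r_{jk})$ with
   $\delta_j$ the column SD and $r$ the Pearson correlation matrix
   (pairwise complete); $w^2_j = S_j/\sum S_j$. Zero-variance columns have
   their undefined correlations set to 0 and end up with weight 0. If
   *every* $S_j$ is zero (fully redundant criteria), the weight is split
   evenly over the varying columns — the symmetric limit of the formula.
4. **Integration**: the default is the self-normalizing product rule
   $W_j = w^1_j w^2_j / \sum_j w^1_j w^2_j$; a convex rule
   $W_j = p\,w^1_j + (1-p)\,w^2_j$ is available with a user-supplied
   preference coefficient $p \in [0,1]$. The source literature also defines
   $p$ by a self-referential expression; since that is circular as printed,
   aquarisk deliberately leaves $p$ to the user. Note the product rule
   *sharpens* non-uniform weights: its only fixed points are uniform
   vectors.
5. **Index**: $Q_j = 100\,(C_j - C^p_j)/(S_j - C^p_j)$ against WHO
   standards $S_j$ with pure-water ideals $C^p_j$ (0 for everything except
   pH, where $C^p = 7$ and $S = 7.5$), and
   $\mathrm{WQI} = \sum_j W_j Q_j$ on the *measured* concentrations.
   Classes: 0–50 excellent, 50–100 good, 100–150 medium, 150–200 poor,
   > 200 extremely poor (all bins lower-inclusive).

Two conventions worth flagging: the pH rating is kept *signed* — a pH of
6.5 contributes −100, exactly as the formula reads, rather than being
folded by absolute value; and classification bins are uniformly `[a, b)`
because the verbal bin definitions in this literature overlap or abut
inconsistently. A computed WQI that lands a floating-point ulp below a
boundary therefore classifies into the lower bin; only the exact boundary
value belongs to the upper one.

## Pollution indices

**HPI** (default metals Fe and Mn): $W_i = 1/S_i$, $Q_i = 100\,C_i/S_i$,
$\mathrm{HPI} = \sum W_i Q_i / \sum W_i$. With every metal at its standard
the index is exactly 100 for any metal set, and it is invariant to a common
rescaling of all $C_i$ and $S_i$. The class scheme is the gap-free
reconciliation [0,15) excellent, [15,30) good, [30,51) intermediate,
[51,76) poor, [76,100) very poor, ≥ 100 unsuitable. Applied to the
published concentration extremes the formula yields values above 1300, far
beyond the summary range printed in the source study; the printed HPI
summary is therefore not a reproduction target, and the equations are
implemented as written.

**Ecological risk**: $E_r^i = T_r^i\, C_i / C^{bg}_i$ and
$\mathrm{RI} = \sum_i E_r^i$, with toxic-response factors Tr (Fe 1, Mn 1,
Cu 5, Zn 1) and *site-specific* background concentrations $C^{bg}$.
Backgrounds are deliberately config-required: the genuine values for any
site are measured, and the shipped example config marks its placeholder
backgrounds (Fe 20, Mn 15, Cu 5, Zn 30 mg/L) as synthetic. RI classes:
< 30 low, 30–60 moderate, 60–120 significant, > 120 very high.

## Deterministic exposure chain

For each metal, route and cohort:

$$\mathrm{CDI_{oral}} = \frac{C \cdot EF \cdot IR}{AT \cdot BW}\,ED,
\qquad
\mathrm{CDI_{dermal}} = \frac{C \cdot ET \cdot EF \cdot K_p \cdot SA \cdot CF}{BW \cdot AT}\,ED,$$

$HQ = \mathrm{CDI}/\mathrm{RfD}$ with the route-matched reference dose
($\mathrm{RfD_{dermal}} = \mathrm{RfD_{oral}} \times ABS$), and hazard
indices both per route (sum over metals) and per metal (oral + dermal).
Exposure profiles: adults IR 2.2 L/day, ED 70 y, EF 350 d/y, ET 0.58 h/d,
SA 18 000 cm², BW 70 kg; children IR 1.8, ED 6, EF 350, ET 1, SA 6 600,
BW 15; CF 10⁻³ L/cm³ for both. The averaging time follows the
non-carcinogenic convention AT = ED × 365 (25 550 / 2 190 days); this
choice is what makes the chain reproduce the published HQ endpoint ranges
to two significant figures, and it implies the oral HQ is independent of ED
(ED cancels). Default toxicity constants: RfD_oral (mg/kg/day) Fe 0.7,
Mn 0.024, Cu 0.04, Zn 0.3; ABS Fe 0.2, Mn 0.04, Cu 0.3, Zn 0.2; Kp (cm/h)
0.001 for Fe/Mn/Cu and 6×10⁻⁴ for Zn. Exceedance flags use strict HQ > 1.

## Monte Carlo simulation

`simulate_hq()` propagates distributions through the same CDI/HQ code:

* **Concentrations**: truncated lognormal on the observed (or published)
  range, with the *truncated* distribution moment-matched to the target
  mean/SD by a two-parameter Nelder–Mead solve on the closed-form truncated
  moments. Matching the untruncated lognormal and then truncating — the
  naive recipe — biases the realized mean low by up to ~10% for skewed
  metals, which would silently shift every simulated HQ. When a sample SD
  is larger than any distribution on the observed range can achieve
  (possible with 2–3 observations), the fit falls back to naive matching
  and records `fit$exact = FALSE`; the generator's own draws use strict
  fitting. An empirical bootstrap family is available as an alternative.
* **Exposure variables**: IR, ED, SA, BW are normal around the
  deterministic value with assumed coefficients of variation 0.10 (0.20
  for ED), truncated at ±3 SD and at 0; EF, ET and CF are point masses.
  The CVs are assumptions (no published dispersion exists) and are echoed
  in the pipeline metadata.
* **Seeding**: one master seed spawns a fixed substream per variable (hash
  of the variable name), so runs are bit-reproducible and adding a metal
  never perturbs the other metals' draws. An explicit seed is required.
* **Calibration**: because HQ is linear in concentration and the inputs are
  independent, the simulated mean HQ equals the deterministic HQ at the
  mean inputs up to Monte Carlo error and the small Jensen terms of 1/BW;
  `calibration_check()` quantifies the relative difference.

A consequence worth stating plainly: with the adult profile the oral Mn
HQ is 1.256 × C, so at the published mean concentration (0.422 mg/L) the
*mean* simulated adult HQ is ≈ 0.53 and cannot exceed 1; only the upper
tail does (the simulated P95 is ≈ 1.6, and roughly a fifth of draws exceed
1, echoing the deterministic exceedance share). Statements that simulated
adult oral Mn risk "exceeds the threshold" can only refer to that tail.
The child cohort's central values do exceed 1 (mean ≈ 2.0).

## The synthetic cohort generator

Raw per-sample data for the motivating 69-well cohort are unpublished, so
`generate_cohort()` emulates the published per-parameter min/max/mean/SD
(16 parameters; truncated lognormal everywhere, truncated normal for pH):

* A **one-factor Gaussian copula** at pairwise correlation 0.8 couples the
  salinity block (TDS, EC, TH, Ca, Mg, Na, K, Cl, SO4), emulating the
  joint salinity signal real cohorts show; pH, HCO3, NO3 and the trace
  metals are independent (their spatial patterns are anthropogenic /
  redox-driven rather than salinity-driven). CO3 is 0. Coordinates, if
  requested, are uniform noise with no spatial structure.
* **Charge-balance repair** then scales anion pools per sample — Cl first
  (largest pool, widest bounds), then HCO3, then all anions, cations only
  as a last resort — to bring the CBE just inside ±5%, clamping to the
  target bounds. Repair is the honest price of demanding electroneutrality
  from marginally-specified draws: ions the repair never touches keep
  their ranks exactly (empirically the cations, SO4 and NO3), while Cl and
  HCO3 — the designated balancing pool — cannot keep their ranks exactly,
  because when an independently drawn HCO3 is itself the charge excess it
  must shrink. Rank correlations for the adjusted ions remain strongly
  positive.
* Two readings of the published summary table were ambiguous in the
  source: the EC row is internally inconsistent as printed (an SD larger
  than the printed range), resolved to min 296 / max 8504 / mean 1755 /
  SD 1458.4 µS/cm as the only physically coherent option; and the Ca
  maximum is taken from the body text (667 mg/L). Both are ordinary
  config-editable targets.

`verify_stats()` checks achieved against target moments with tolerances
that scale like $1/\sqrt{n}$ (anchored at 3%/10% at n = 10 000) *plus* a
3-standard-error sampling allowance — without the allowance, a heavy-tailed
parameter like NO3 (cv ≈ 2.7) would be flagged for pure sampling noise in
small cohorts. At n = 10 000 the 3% mean band is itself only ~1.1 Monte
Carlo SE for NO3, so a single draw can legitimately miss it; the test suite
keeps that assertion at its stated width and documents the miss rather than
widening it.

**What a green test does and does not establish.** The generator matches
univariate moments, the salinity-block correlation, and the CBE gate. It
does not reproduce the real cohort's full dependence structure (notably
metal–ion dependence and EC/TDS proportionality beyond the copula), any
spatial autocorrelation, or the actual per-sample co-occurrence of metals —
so cohort-level results that depend on joint extremes (e.g. the real
study's WQI/HPI category percentages) are *not* reproduction targets, and
the package does not present them as such.

## Known limitations

* No saturation-index / geochemical speciation modelling, no multivariate
  source apportionment (PCA/HCA), no spatial interpolation or mapping.
* No carcinogenic risk (slope factors) and no inhalation route.
* The Piper/Gibbs/Sulin rules are deterministic digitizations of diagrams
  normally read graphically; near thresholds the labels are sharp where a
  human reader would hedge.
* Monte Carlo inputs are drawn independently; no copula between exposure
  variables and concentrations is offered because no dependence data
  exist.
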