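---
title: "Models and methods behind rumenferm"
author: "rumenferm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rumenferm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenferm)
```

# Scope

`rumenferm` analyses *in vitro* gas-production studies of ruminant feeds:
serum bottles containing a feed substrate, buffered rumen fluid and a
reducing agent are incubated at 39&nbsp;°C, cumulative gas is recorded over
time, and at the end of incubation the residue weight and the volatile
fatty acid (VFA) profile of the liquor are measured.  The package covers
the computational chain from raw bottle readings to reported tables:

1. blank correction and normalization to incubated organic matter (OMCV),
2. sigmoidal kinetic modelling with maximum-rate summaries,
3. stoichiometric partition of fermentation gas into CO~2~ and CH~4~,
4. nutritive-value equations (NSC, metabolizable energy, OM degradability),
5. the factorial ANOVA layer with Tukey HSD letter groupings, and
6. a synthetic-study generator with known ground truth.

Wet-lab procedure (proximate analysis, tannin assays, chromatography,
inoculum handling) is out of scope; compositions and secondary metabolites
enter only as numeric annotations.

# The kinetic model

Cumulative gas per gram of incubated organic matter is modelled with the
three-parameter sigmoidal (Groot-type) curve

$$G(t) = \frac{A}{1 + (B/t)^{C}},$$

where $A$ (mL/g) is the asymptotic gas production, $B$ (h) is the time at
which half of $A$ is reached, and $C$ (dimensionless) is the curve-switch
parameter controlling how abruptly fermentation accelerates.  $G$ is 0 at
$t = 0$ (the model limit), strictly increasing, equals $A/2$ exactly at
$t = B$, and approaches $A$.  For $C > 1$ the rate $G'(t)$ has an interior
maximum at

$$T_{max} = B\left(\frac{C-1}{C+1}\right)^{1/C}, \qquad
R_{max} = \frac{A\,C\,B^{C}\,T_{max}^{-C-1}}{\left(1 + B^{C} T_{max}^{-C}\right)^{2}},$$

while for $C \le 1$ the rate is maximal as $t \to 0^{+}$ and
`computeTmax()` / `computeRmax()` refuse to answer rather than report a
boundary artefact.  Both closed forms are property-tested against a dense
numerical-derivative oracle (central differences on a 20,000-point grid),
which keeps the implementation honest independently of any algebra.

## Fitting

`fitGroot()` minimizes unweighted least squares on cumulative volumes with
a bounded Levenberg–Marquardt optimizer (`minpack.lm::nlsLM`).  Starting
values and bounds are deterministic functions of the data — $A_0 = 1.1
\max g$, $B_0$ the earliest time with $g \ge A_0/2$ (median time as a
fallback), $C_0 = 1.5$, bounds $A \in (0, 3\max g]$, $B \in (0, 2\max t]$,
$C \in [0.05, 10]$ — so a fit is reproducible from the curve alone.
Non-convergence is reported through a flag, never silently.  At least four
points are required for a three-parameter fit.  Fits are per bottle;
substrate-level summaries average per-bottle parameters, so bottle-to-bottle
variation propagates into the SEMs rather than being averaged away before
fitting.

Negative blank-corrected readings are *retained* for fitting (truncation
at zero would bias $A$ downward) but counted and reported.  Pressure-to-
volume calibration is out of scope: the package ingests volumes.

# Blank correction and OMCV

Each gas run includes blank bottles (inoculum and buffer, no substrate).
`blankCorrect()` subtracts, at every recording time, the mean reading of
the same run's blanks; run-wise correction removes the between-run
component of inoculum activity.  `toOMCV()` divides by the bottle's
incubated organic matter, giving mL per g OM — the scale on which the
kinetic model is fitted and gas totals are reported.

# Gas partition from VFA stoichiometry

Fermentation of hexose to acetate (a) and butyrate (b) releases hydrogen,
which methanogens convert to CH~4~; propionate (p) formation consumes
hydrogen.  With molar amounts in mmol per g of incubated substrate:

$$\mathrm{CO_2} = a/2 + p/4 + 1.5\,b, \qquad
\mathrm{CH_4} = a + 2b - \mathrm{CO_2}.$$

The identity $\mathrm{CO_2} + \mathrm{CH_4} = a + 2b$ holds exactly and is
property-tested over 10,000 random profiles.  Iso-acids and valerate
contribute to the VFA total but not to the partition.  A
propionate-dominated profile can drive the CH~4~ estimate negative; the
value is returned with a warning, never clamped, because clamping would
silently destroy the stoichiometric algebra.  Volumes use a configurable
molar volume, 25.59 mL/mmol by default (ideal gas at 39&nbsp;°C, 1 atm).

A unit caveat worth stating plainly: end-point VFA concentrations reported
per gram of substrate ("mM/g") are treated as mmol/g by the formulas.  If
the concentrations actually refer to the fermentation liquor, absolute
CH~4~ volumes scale by the liquor volume and can exceed the measured gas
volume by an order of magnitude; published tables built this way are
internally consistent only for *ratios* (CH~4~ as % of total gas), which is
why the package's cross-checks against published cells are ratio
identities, not absolute volumes.

# Nutritive value

* **NSC** (% DM) by difference: $100 - (\mathrm{NDF} + \mathrm{CP} +
  \mathrm{EE} + \mathrm{Ash})$; the complement identity is exact by
  construction and tested.
* **Metabolizable energy** (MJ/kg DM) by the Menke–Steingass regression
  $ME = 2.2 + 0.1357\,GP + 0.0057\,CP + 0.0002859\,CP^2$, with $GP$ the
  blank-corrected 24 h gas scaled to 200 mg incubated DM.  Published uses
  of this regression are ambiguous about the CP unit (% DM vs g/kg DM,
  a tenfold difference that the quadratic term amplifies); the function
  therefore *requires* an explicit unit declaration and substitutes the
  value as declared, with no silent conversion.  The reporting pipeline
  declares % DM, the only choice that yields forage-typical energies
  (6–10 MJ/kg DM) at realistic gas productions.
* **dOM** (%): $100 (\mathrm{OM_{in}} - \mathrm{OM_{res}}) /
  \mathrm{OM_{in}}$ from incubated and residue organic matter.

Report tables round to 3 significant figures with ties away from zero
(`signifHalfUp()`), mimicking how such tables are printed.

# Statistical layer

Responses are assembled into a long bottle-level table.  Replicates from
the two gas runs are pooled (the run factor is dropped), matching the
analysis convention of the designs emulated here; a run-effect check is a
one-liner via `oneWayAnova(tab, resp, group = "run")`, and on synthetic
data generated without a run effect it is non-significant at the nominal
rate.

* **One-way ANOVA** (substrate effect) with pooled
  $SEM = \sqrt{MS_{within}/n}$ under balance.
* **Two-way factorial ANOVA** `value ~ cut * part`.  The interaction term
  is included deliberately: factorial reports of such studies list an
  interaction p-value, and the fitted model should be the reported model.
  Letters compare the four plant parts within each cut, using the
  full-model residual mean square.
* **Tukey HSD letters.**  Pairwise adjusted p-values come from the
  studentized range distribution (`ptukey`; harmonic-mean n under
  imbalance, flagged).  The compact letter display uses the standard
  insert-and-absorb algorithm; its defining contract — two groups share a
  letter *iff* their adjusted p ≥ α — is verified by brute force over all
  pairs in the tests, and the p-values themselves are cross-checked
  against `stats::TukeyHSD`.  The type-I error of the whole one-way
  pipeline is calibrated over 2,000 null simulations.
* **Shapiro–Wilk screening** flags non-normal responses; degenerate
  (constant) inputs are reported as such, with no transformation applied —
  screening is diagnostic, not corrective.

# The synthetic-study generator

`simulateStudy()` produces complete bottle-level studies with known ground
truth, so that every stage of the pipeline can be tested against what it
should recover.  The two ready-made designs emulate the layouts this
package is aimed at:

* `exp1Config()`: 5 substrates (two fresh cuts, two pelleted, one hay),
  3 replicate bottles × 2 gas runs, 2 blanks per run, 120 h horizon, gas
  recorded every 2 h to 24 h and then at 30, 36, 48, 72, 96, 120 h (a
  dense early grid where the curvature lives).
* `exp2Config()`: 8 substrates (2 cuts × 4 plant parts), 2 replicates ×
  2 runs, 24 h horizon, 2 h grid.

The true parameters are fixed at the published group-mean scale for sulla
forage: asymptotes 218–250 mL/g for the 120 h design, with $(B, C)$
solved once so that the closed-form $T_{max}$/$R_{max}$ reproduce the
published kinetic magnitudes (0.27–3.69 h, 6.2–10 mL/h); degradabilities
0.49–0.66; six-acid VFA means at the published per-acid values; 24 h
asymptotes back-solved from 24 h OMCV at shared $B = 16$ h, $C = 1.2$
(no published kinetics exist for plant parts).  These defaults are the
study conditions, not tuning knobs.

Noise model, chosen for simplicity under the right constraints:

* gas readings: additive Gaussian (default s.d. 2 mL, the scale implied by
  a gas SEM of ~0.9 mL/g at n = 6), truncated at 0 — readings are
  non-negative but curves may be locally non-monotone, as real transducer
  series are;
* blank gas: a per-run constant drawn once per run (mean 10 mL, s.d. 1 mL)
  plus per-reading noise, so run-wise blank correction has something real
  to remove;
* VFA end-points: log-normal about the true means (mean-preserving;
  CV 5% for the 120 h design, 8% for the 24 h design, the scales implied
  by the published SEMs) — concentrations are positive and right-skewed;
* degradability: Gaussian on the dOM fraction (s.d. 0.02, matching an SEM
  of ~0.9 percentage points at n = 6), truncated to (0, 1);
* incubated DM: Gaussian, 1.0040 ± 0.0028 g.

Every bottle draws from its own seeded substream derived from the master
seed, so regenerating a study is exactly reproducible bottle by bottle.

What the generator does *not* emulate: microbial dynamics, pH feedback,
substrate-by-inoculum interactions, autocorrelated transducer drift, or
any mechanistic link between composition, kinetics and VFA profiles (each
is specified independently).  Passing tests therefore demonstrate that the
*computational chain* is correct and calibrated — recovery of known
parameters, exact identities, nominal error rates — not that the
phenomenological truth tables are an adequate biological model.

# Numerical choices and edge cases

* `GasCurve` requires ≥ 4 strictly increasing positive times; decreases
  beyond a tolerance set a non-monotonicity flag rather than an error.
* Fit determinism: identical curves (in any point order) give identical
  fits; the optimizer never uses random restarts.
* $T_{max}/R_{max}$ at $C \le 1$: a domain error, by design.
* Zero within-group variance in ANOVA: p-values are reported as 1 and
  letters are assigned by exact mean equality, avoiding 0/0 F statistics.
* CSV interchange writes doubles at 17 significant digits, so files
  round-trip bit-exactly; re-running the pipeline on the same inputs and
  seed reproduces byte-identical outputs.

# Problem sizes used by the test-suite simulations

Calibration checks use sizes chosen to make their Monte-Carlo error small
relative to the asserted bands: 10,000 profiles for the conservation
identity, 1,000 parameter sets for the closed-form/numerical-derivative
agreement, 200 noisy curves for fitter unbiasedness, 2,000 null data sets
for the type-I error of the ANOVA pipeline, and 100 seeds for the letter-
pattern simulation.

# Known limitations

* The gas model is single-pool with no lag phase; feeds with pronounced
  lag or multiphasic fermentation need a different model family.
* The stoichiometric partition ignores hydrogen sinks other than
  propionate (no biohydrogenation, no sulfate reduction) and treats the
  VFA pool as entirely fermentative.
* The ANOVA layer is fixed-effects only and applies no multiplicity
  control across responses, matching the reporting convention it
  reproduces.
* Condensed tannins and total polyphenols are carried as annotations; no
  dose–response modelling is attempted.
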