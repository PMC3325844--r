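---
title: "Models and methods behind phaomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phaomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaomics)
```

phaomics analyses dual-nutrient-limited chemostat cultures of
polyhydroxyalkanoate (PHA) producing *Pseudomonas putida*. This vignette
explains the models the package implements, the parameters that matter and
their defaults, what the synthetic-study generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Steady-state physiology

### Elemental accounting

All nutrient bookkeeping is done in **elemental grams** (g C, g N), not in
substrate grams. The feed carries decanoate (interpreted as decanoic-acid
equivalents, MW 172.26 g/mol, 10 carbon atoms) and ammonium chloride
(53.49 g/mol, one nitrogen). This is the only convention under which a
culture table's yield coefficients, feed ratios and cell dry weights are
mutually consistent, and it makes the molar feed ratio

$$ C_0/N_0 = \frac{n_C}{n_N} \quad [\mathrm{mol\,mol^{-1}}] $$

a pure number comparable across substrates. Residual broth concentrations
are likewise elemental; values below the detection limit (1.9 mg N/l for
the ammonium assay) enter the arithmetic as zero with the limit retained
as an annotation.

### Yields, rates and the dual-limitation borders

At steady state, with dilution rate $D$ equal to the specific growth rate,
the yield coefficients are

$$ Y_{X/C} = \Delta X / \Delta C, \qquad Y_{X/N} = \Delta X / \Delta N
   \quad [\mathrm{g\,g^{-1}}], $$

where $\Delta X$ is the **total** CDW (stored polyester included) and
$\Delta C$, $\Delta N$ the consumed elemental masses. Specific rates
divide by the PHA-free (residual) biomass $X_{\mathrm{PHA-free}} =
X(1-f)$, with $f$ the PHA fraction of CDW:

$$ q_C = \Delta C \cdot D / X_{\mathrm{PHA-free}}, \qquad
   q_{PHA} = PHA \cdot D / X_{\mathrm{PHA-free}}. $$

Following the Egli dual-limitation model, the critical feed ratio at which
a culture exhausts carbon and nitrogen simultaneously is

$$ C_0/N_0 \cong \frac{Y_{X/N} \cdot 14}{Y_{X/C} \cdot 12}, $$

computed with the integer element masses 12 and 14 — the form in which
this quotient is conventionally written. Everywhere else the package uses
12.011/14.007; the difference is below 0.1% and both constant sets are
exposed by `elemental_constants()`. The carbon-limited culture's yields
give the lower (carbon-side) border, the nitrogen-limited culture's the
upper border; `physiology_summary()` generalizes this to the smallest and
largest per-condition boundary. Ratios on the borders classify as
**dual**: the borders are the edges of the dual region, so the interval is
closed.

### Carbon balance

Consumed carbon (C-mol/l) is split between PHA-free biomass (27 g per
C-mol, a fixed composition assumption), polyester carbon (via the monomer
composition and the polymer repeat-unit masses C6 = 114.14, C8 = 142.20,
C10 = 170.25 g/mol with 6/8/10 carbons) and CO~2~ (the evolution rate over
$D$). The CO~2~ evolution rate is derived from the off-gas fraction as

$$ CER = F \cdot 60 \cdot (y_{out} - y_{in}) / V_m / V \quad
   [\mathrm{C\text{-}mol\,(l\,h)^{-1}}], $$

with molar volume $V_m$ = 24.45 l/mol (25 °C, 1 atm) and ambient inlet
CO~2~ fraction 0.0004 by default; no off-gas formula is standardized for
this instrument class, so these are explicit, overridable choices. Closure
(outputs over inputs) should be 1; values above 1.05 raise a warning
rather than an error, since over-closure signals measurement bias, not a
computational fault.

### Steady-state detection

A culture is steady once every monitored channel (OD, dissolved O~2~,
off-gas CO~2~) stays within a relative drift tolerance of its window mean
over a window of four residence times ($4/D$). The tolerance (default 5%)
is a configuration knob: the underlying experimental criterion is
qualitative ("constant"), so the detector makes it operational. The
detector scans every sampled window start and reports the earliest steady
window as well as the trailing-window verdict. With the canonical
first-order wash-in $x(t) = x_{ss}(1-e^{-Dt})$ the earliest steady window
starts near $\ln(20)/D$ and a full window is therefore confirmed between
5 and 8 residence times — matching the practical observation that five to
eight residence volumes are needed before sampling.

## PHA quantification from GC peak tables

Monomer methyl esters are quantified by single-point internal-standard
calibration against 3-methylbenzoic acid (mass$_m$ = area$_m$/area$_{IS}
\times m_{IS} \times rf_m$), with unit response factors by default —
per-analyte factors are configurable but no published calibration curves
exist to seed them. Quantities are expressed as **polymer repeat-unit
equivalents** (what culture tables report), not methyl-ester masses.
Composition is scale invariant; the PHA content scales linearly with total
monomer mass.

## Differential expression

Two-channel array intensities are background-corrected by subtraction with
a **half-minimum floor** (per array and channel), log2-ratioed and
median-centered per array; replicate log ratios then get a one-sample
t-test and Benjamini–Hochberg adjustment (`stats::p.adjust`, verified in
the test suite against an independent brute-force step-up oracle). This
replaces model-based background correction, variance stabilization and
moderated statistics on purpose: those internals belong to the upstream
microarray toolchain, while this package needs a transparent, testable
reduction whose operating characteristics on planted data are provable.
The trade-off is acknowledged: a plain t-test at n = 3 has heavier-tailed
null behaviour than a moderated one, which is why the planted-data
acceptance checks quantify FDR and recall directly.

Calls use the standard thresholds: transcripts are up/down when the fold
change **strictly exceeds** 2 in either direction at adjusted p < 0.05
(the wording "exceeded 2" implies strict inequality); a stricter secondary
filter (fold > 3.5, raw p < 0.03) isolates the strongest responders
between closely related conditions. Protein spots use **inclusive** ratio
bounds (≥ 2-fold up, ≤ 0.5-fold down, "or higher/lower") at p < 0.05 from
a Welch t-test on log spot volumes across triplicate gels — the original
spot statistics are unnamed, so an unequal-variance test is the safe
default. Presence/absence spots pass through as "only in condition" calls.
Fold changes display in the signed convention (−6.7 means 6.7-fold down).

Cross-omics integration intersects DE locus tags between comparisons and
counts transcript–protein concordance as agreement of non-ns directions,
with presence-in-test counting as up.

## Metabolomics

Retention times convert to Kovats retention indices by piecewise-linear
interpolation on an n-alkane ladder (C10–C36; alkane $n$ defines RI
$100n$) — the linear, temperature-programmed form, since the conversion is
named but not specified in typical deconvolution software configurations.
Spectral similarity is the cosine over the union of integer m/z bins of
square-root-scaled intensities, the classic library match factor; the
acceptance rule is match ≥ 0.75 (inclusive) within an RI window of ±5
units (a configurable default; no tolerance is published for the original
configuration). Abundances normalize by the ribitol internal-standard area
and the sampled cell dry weight.

QC follows the RSD convention: technical RSD across samples from one
fermentor, biological RSD across independent cultivations; metabolites
whose biological RSD exceeds a ceiling (default 50%, just above the
largest RSD retained in practice) are excluded from level calls. Pearson
correlations between condition profiles are computed on log10 mean
abundances to stabilize variance across the wide dynamic range. Level
changes against the reference condition use a 1.5-fold threshold with QC
gating — published level-change tables are qualitative, so the threshold
is a documented knob, not a fitted constant.

## The synthetic-study generator

`simulate_study()` builds a complete three-condition study (carbon, dual,
nitrogen limitation at D = 0.1 h⁻¹, three biological replicates) whose
ground truth is known: feeds are chosen so the conditions fall into the
three regimes of the planted boundary model, steady states are constructed
to **close the carbon balance exactly** before noise, GC peak tables
encode the planted monomer compositions, arrays carry symmetric planted
log2 effects, gel spots link to the transcript truth (including
presence/absence spots), and metabolite peaks are placed at
inverse-interpolated retention times of the planted retention indices with
a planted up/down/absent pattern of two-fold changes.

Noise is **multiplicative lognormal with unit mean** everywhere — the
simplest model consistent with RSD-style QC reporting, and unbiased so
planted values are recovered in expectation. Defaults
(`default_noise()`):

* CDW and PHA fraction 3%, residuals 5% — the scale of printed
  physiology measurement errors (e.g. CDW 4.63 ± 0.14);
* online trace channels 0.5% — representative of OD-probe/gas-analyzer
  stability, and the only regime under which a 5% drift criterion is
  meaningful;
* metabolite abundances 22% technical and 32/28/49% biological RSD for
  the carbon/dual/nitrogen conditions — the study-scale reproducibility
  figures;
* array replicate log2-ratio sd 0.08 — technical-replicate precision for
  same-slide two-channel ratios, chosen by power arithmetic so that a
  3-replicate t-test has high recall for 4-fold effects (at sd 0.08 the
  t statistic for a 4-fold effect is ≈ 43 in expectation and the
  BH-significance requirement fails only when the sample sd more than
  doubles, probability ≈ 1%);
* 2-D gel spot volumes 15%, GC areas 2%.

The generator enforces the study's accounting identities; it is **not** a
mechanistic model. It does not emulate growth kinetics, probe-specific
array biases, dye swaps, chromatographic co-elution (peaks arrive
deconvolved), retention-time drift, or missing-at-random measurements.
Passing tests on synthetic data therefore demonstrate that the reduction
pipeline is correct and well calibrated under the stated noise model — not
that it is robust to every artifact of real instruments. The built-in
metabolite library is synthetic: literature-scale retention indices with
deterministic artificial fragment spectra, suitable for exercising
annotation logic only.

## Numerical choices and degenerate inputs

* Yields and rates refuse non-positive consumption or zero residual
  biomass with errors naming the offending quantity.
* A zero-nitrogen feed makes the molar ratio undefined and is an error.
* Background-corrected intensities are floored at half the smallest
  positive value per array/channel, so log ratios are always finite.
* Degenerate t-tests (zero replicate variance) return p = 1 for a zero
  mean and p = 0 otherwise rather than NaN.
* Annotation ties at equal match factor break to the smaller RI distance,
  then to library order.
* Off-gas CO~2~ below the inlet level is clipped to zero with a warning.
* Boundary values of the dual-limitation interval classify as dual;
  threshold ties follow each rule's wording (strict for transcripts,
  inclusive for proteins and the 0.75 match rule).

## Problem sizes used in the validation suite

The shipped tests validate the pipeline at study scale: the planted-FDR
and recall checks use 100 simulated array datasets of 10,000 features ×
3 replicates; yield recovery uses 100 seeded replicate studies; the
steady-state detector is compared against an exhaustive window-scan
oracle on 200 randomized traces; BH adjustment is compared to a
brute-force step-up on 1,000 random vectors. These sizes give
Monte-Carlo standard errors well below the decision margins of each
check while keeping the full suite runnable in well under a minute per
stage.

## Known limitations

* The DE stage is a reduction of a published array analysis, not a
  re-implementation of its toolchain; real-data gene lists produced with
  moderated statistics will differ in the tail.
* Single-point IS calibration assumes response linearity; per-monomer
  response factors must be supplied for instrument-grade accuracy.
* The 27 g/C-mol biomass composition is fixed; organisms or conditions
  with markedly different elemental composition need a different
  constant.
* Retention-index extrapolation beyond the alkane ladder is linear from
  the end segments and flagged, but inherently less reliable.

## A worked run

```{r demo, eval = FALSE}
study <- simulate_study(seed = 42)
summ <- physiology_summary(study$feed, study$steadystate)
summ
attr(summ, "borders")

de <- call_transcript_de(
  de_test(normalize_and_logratio(study$arrays$n_vs_c$arrays)))
attr(de, "summary")
```
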