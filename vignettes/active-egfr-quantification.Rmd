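---
title: "Quantifying active EGFR by fluorogenic-probe flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active EGFR by fluorogenic-probe flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeEGFR)
```

## The measurement problem

EGFR tyrosine-kinase inhibitors (TKIs) help the subset of non-small-cell
lung cancer (NSCLC) patients whose tumours depend on activated EGFR
signalling. The standard companion test is genotype: exon 21 L858R and exon
19 deletions activate the kinase constitutively and predict TKI benefit. But
genotype is an imperfect proxy for what the drug actually binds -- a
catalytically competent, ATP-pocket-accessible kinase conformation -- and
20--30% of mutation-positive patients do not respond.

This package implements a functional alternative: a TKI pharmacophore
carrying an environment-sensitive fluorophore that is almost dark in water
and turns on inside the hydrophobic kinase pocket. Dissociated tumour cells
are stained with the probe together with a total-EGFR antibody and a CD45
leukocyte marker, and read by multicolor flow cytometry. The fraction of
cells that are both antibody-positive and probe-positive -- "active-EGFR"
cells -- is the assay's readout. The package covers the full analysis chain:
the binding/brightness model, a synthetic event simulator, the gating
strategy, diagnostic-performance statistics on the packaged clinical
cohorts, and a cost model for using the assay as a cheap triage in front of
sequencing.

## Binding and brightness model

Probe--kinase binding is treated as a reversible equilibrium. With probe
concentration $P$, probe dissociation constant $K_d$, and a competing
ATP-pocket inhibitor at concentration $I$ with dissociation constant $K_i$,
the occupied fraction of active-conformation receptors is the competitive
isotherm

$$\theta = \frac{P}{P + K_d\,(1 + I/K_i)},$$

which reduces exactly to $P/(P+K_d)$ without competitor. The assay's
working concentrations are 5 µM probe and, in the specificity-control tube,
50 µM gefitinib. Measured $K_d$ values span 0.8 µM (L858R) to 2.7 µM
(wild-type); cellular apparent values (e.g. 2.1 µM) are treated as
interchangeable inputs, since nothing downstream distinguishes the two.

Gefitinib's own $K_i$ is never measured in the assay, so the default
(0.5 µM) is an order-of-magnitude choice made once: at the working
concentrations it suppresses ≥85% of probe occupancy, consistent with the
observed strong reduction of labeling after gefitinib preincubation. It is
a configurable parameter of `binding_params()` and `assay_model()`, not a
constant.

Per-cell brightness is affine in bound probe:

$$\mathbb{E}[\mathrm{signal}] = a + g\,\frac{\phi_\mathrm{bound}}{\phi_\mathrm{free}}\; n_\mathrm{active}\,\theta,$$

with autofluorescence floor $a$, detection gain $g$, and the turn-on
contrast given by the bound/free quantum-yield quotient. The free-state
yield is the PBS measurement (5.8%); no protein-bound yield exists, so the
bound state is proxied by the DMSO measurement (42.4%), giving a 7.31-fold
contrast. This proxy is a documented approximation -- the true pocket
environment may be more or less polar than DMSO -- but only the product
$g\,\phi_\mathrm{bound}/\phi_\mathrm{free}$ matters to the simulator, so any
error is absorbed by the arbitrary-unit gain.

`saturation_binding_fit()` and `fit_ic50()` recover $K_d$/$B_{max}$ and
four-parameter-logistic IC50s from titration data. Both use trust-region
Levenberg--Marquardt least squares parameterised on log-concentration
(log-scale parameters keep the search away from the boundary and make the
Wald interval for IC50 sensible), with starting values from the data
extremes and the geometric-mean concentration. Degenerate inputs (constant
response, too few concentrations, non-convergence) raise explicit
fit-failure errors rather than returning garbage.

## The synthetic specimen simulator

Real dissociated-tissue specimens cannot ship with a package, so every
downstream stage is exercised against `simulate_panel()`, which draws
per-event channel values for the four matched tubes of one specimen:

* **DMSO control** -- antibodies but no probe: the probe channel is pure
  autofluorescence;
* **isotype control** -- probe but antibody background only;
* **stained** -- probe at 5 µM, occupancy from the isotherm;
* **gefitinib-blocked** -- probe plus 50 µM competitor.

A specimen is a mixture of `population_spec()` archetypes: mutant tumour
cells with high `active_fraction`, autoinhibited wild-type tumour cells
(few active receptors regardless of expression), EGFR-overexpressing
wild-type cells, normal epithelium, CD45-bright leukocytes, and low-scatter
debris. Each population carries log-normal scatter parameters, a log10-normal
per-cell receptor count, and an apparent $K_d$. Events are labelled with
their population and a truth-active flag (`active_fraction >= 0.5`), so
recovery of the simulated truth by the gating pipeline is directly testable.

Noise is multiplicative log-normal with CV 25% on every specific signal plus
an additive Gaussian background floor, truncated at zero. No event-level
noise measurements exist for patient tissue; the 25% CV was chosen once to
produce clearly bimodal dot plots resembling the published ones and is
exposed in `assay_model()`. Biopsy panels default to 10^4 events and
surgical panels to 10^5, echoing the live-cell yields typical of each
specimen route.

What the simulator deliberately does **not** model: spectral spillover and
compensation (channels are treated as already compensated), doublets,
instrument drift, viability staining, and area/height/width parameters. Two
consequences matter for interpretation. First, because the DMSO tube
carries full antibody staining and the background correction subtracts raw
DMSO percentages for all three parameters, the corrected antibody-positive
percentage of a *simulated* panel is always near zero -- the large corrected
EGFR(+) values of real specimens live only in the packaged cohort tables.
Second, a passing recovery test says the pipeline is internally consistent
under these assumptions, not that the assay works on tissue; the clinical
evidence enters through the packaged cohorts instead.

## Gating strategy

`quantify()` implements the six-step strategy: (i) scatter floor removes
debris; (ii) CD45-high events are excluded; (iii) positivity thresholds are
set so the control tubes contain no positive events -- the probe cut from
the DMSO tube, the antibody cut from the isotype tube; (iv) quadrants of the
antibody-vs-probe dot plot give the three parameters, EGFR(+) = Q1+Q2,
HX103(+) = Q2+Q3, double-positive = Q2, as percentages of gated cells;
(v) the stained-tube percentages are background-corrected by subtracting the
DMSO-tube percentages; (vi) the blocked tube yields the specificity check.

Numerical choices, all in `gate_config()`:

* "No positive control events" is the control-tube **maximum**
  (`control_quantile = 1`). A quantile of 0.999 is the recommended robust
  alternative when single-event outliers are a concern; the contract is the
  linearly interpolated percentile either way.
* Positivity is **strict** (`value > cut`); an event exactly at the cut is
  negative, the conservative reading of the no-positive-events rule.
* The CD45 cut is an absolute instrument-scale value from the configuration
  (like the scatter floors, it cannot be portable across instruments). If
  set to `NULL` it is derived as a quantile of the isotype tube's CD45
  signal -- sensible only when the panel has no dominant CD45-high
  population.
* Background correction is a plain subtraction of percentages. Printed
  cohort values as low as −3.5% confirm subtraction (a re-thresholding
  scheme could never go negative).
* MFIs are arithmetic means of the probe channel over gated events, on the
  untransformed scale; whether the original histograms showed means or
  medians is unknowable from the text, and the mean was chosen and is stated
  here.
* The blocking ratio is
  $1 - (\mathrm{MFI}_\mathrm{blocked} - \mathrm{MFI}_\mathrm{DMSO}) /
  (\mathrm{MFI}_\mathrm{stained} - \mathrm{MFI}_\mathrm{DMSO})$, clamped to
  $[0,1]$; when the stained tube shows no signal above DMSO the ratio is
  reported as not evaluable (`NA`), not as an error.

## Diagnostic performance

`roc_auc()` computes the AUC twice -- as the trapezoidal area under the
empirical ROC and as the tie-corrected pair statistic
$(\#\{x_+ > x_-\} + \tfrac12\#\{x_+ = x_-\})/(n_+ n_-)$ -- and asserts the
two agree on every call; exact cross-class ties contribute one half. The
standard error is Hanley--McNeil and the 95% interval is the uncapped Wald
interval (published intervals with upper bounds above 1 show no truncation
was applied). `youden_cutoff()` searches midpoints between consecutive
distinct values for the maximum of $J = \mathrm{sens} + \mathrm{spec} - 1$
under the rule "positive if value ≥ cutoff", breaking exact $J$ ties toward
sensitivity. `confusion()` applies the same ≥ rule and attaches exact
Clopper--Pearson intervals (beta quantiles) to sensitivity, specificity and
accuracy. `mann_whitney()` is exact (null distribution of U) for
`min(n, m) <= 8` without ties and a tie-corrected normal approximation
otherwise. No multiple-testing correction is applied anywhere, matching the
original analysis. `display_round()` rounds half away from zero for echoing
values next to their printed one-decimal forms; analyses always use full
precision.

Two published figures resist exact recomputation from the printed
per-patient tables, and the package reports rather than hides this
(`reproduce()` carries both in its checklist):

* the Mann--Whitney p for the antibody parameter in the response analysis
  is printed as 0.1007 but recomputes as 0.1063 under the exact test (no
  standard variant reproduces 0.1007); both values mean the same thing --
  no significant difference;
* the published antibody-parameter cut-off of 36.3% is not the Youden
  optimum of its own table: exhaustive search over all midpoints finds
  $J = 0.742$ at 62.05 versus $J = 0.735$ at 36.25. The other two published
  cut-offs (30.1%, 31.0%) are exact Youden optima. All published operating
  characteristics use the published thresholds and reproduce exactly, so
  `confusion()` is always evaluated at those thresholds.

The printed summary table also disagrees by one patient with a direct
count of the per-patient table at the 30.1% threshold (10 vs 11
mutation-positive patients above threshold); `validate_summary()`
recomputes every derivable cell and flags exactly that bucket.

## Cost model

The decision model prices testing only. Sequencing-only costs $C_N$ per
patient. Probe-first triage costs $C_F$ plus, for the FACS-negative
fraction, $C_N$ on top, so with FACS-positive probability
$p = \pi s + (1-\pi)(1-sp)$ the expected cost is $C_F + (1-p)\,C_N$ and the
break-even cost ratio is $r^* = 1/p$ -- with perfect specificity,
$1/(\pi s)$. At the biopsy-cohort operating point ($s = 0.733$, $sp = 1$)
this gives $r^* \approx 2.7$ at 50% prevalence (Asian cohorts) and 9--14
at 10--15% prevalence (US/European cohorts). The model deliberately ignores
treatment costs and the consequences of misclassification; it answers only
"when is the cheap test worth running first", and `breakeven_sweep()` maps
that answer over prevalence and sensitivity grids.

## Problem sizes and test design

The package's own verification uses: exhaustive enumeration oracles for the
Youden search and the exact Mann--Whitney path; an independent ROC package
as a cross-check of the AUC on random tie-rich inputs; 10,000-replicate
binomial simulations for Clopper--Pearson coverage at $n = 12$; and a
nine-point truth grid (active shares 0.1--0.9) at 10^5 events per tube for
simulator-to-gating recovery, asserting corrected double-positive within
±5 percentage points of truth and strict monotonicity. These sizes were
chosen as the smallest at which the stochastic checks are comfortably
stable under their fixed seeds.

## Limitations

The simulator is a statistical stand-in, not an instrument model; its
defaults (channel scales, noise CV, population archetypes) are stated
assumptions, and conclusions about real tissue rest on the packaged cohort
tables, which are small (23 and 31 patients, single-site). The binding model
is equilibrium-only -- no kinetics, no irreversible binding -- and the cost
model prices no clinical consequences. The clinical thresholds (30.1%,
36.3%, 31.0%) were derived on surgical specimens; biopsy specimens yield
about a hundredfold fewer cells and may warrant different cut-offs.
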