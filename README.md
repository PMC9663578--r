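# activeEGFR

Quantification of conformationally **active EGFR** in dissociated tumour
specimens by multicolor flow cytometry with a turn-on fluorogenic
kinase-inhibitor probe -- and evaluation of that readout as a companion
diagnostic for EGFR-TKI therapy in non-small-cell lung cancer.

Genotype (EGFR L858R / exon-19 deletion) is the standard predictor of TKI
benefit, but it is a proxy: the drug binds a catalytically active kinase
conformation, not a DNA sequence. The assay modelled here stains single-cell
suspensions with a TKI-based probe whose environment-sensitive fluorophore
lights up inside the hydrophobic ATP pocket, alongside a total-EGFR antibody
and a CD45 leukocyte marker. The package is for analysts working with (or
simulating) such data: it implements the binding model, the gating strategy,
the diagnostic statistics, and the testing-cost model, with the published
surgical (n = 23) and biopsy (n = 31) cohort tables packaged as validated
fixtures.

## The model in brief

* **Occupancy.** Probe binding follows the competitive isotherm
  θ = P / (P + K_d (1 + I/K_i)); the blocked control tube (50 µM gefitinib
  vs 5 µM probe) suppresses occupancy and provides the specificity check.
* **Brightness.** E[signal] = a + g (φ_bound/φ_free) n_active θ, a 7.3-fold
  turn-on contrast from the measured quantum yields (5.8% free in PBS, 42.4%
  as the bound-state proxy).
* **Gating.** Scatter floor → CD45 exclusion → positivity cuts placed so
  control tubes contain no positive events → quadrant percentages
  EGFR(+) = Q1+Q2, HX103(+) = Q2+Q3, EGFR(+)HX103(+) = Q2 → background
  correction by subtracting the DMSO-tube percentages → blocking ratio from
  probe-channel MFIs.
* **Diagnostics.** Tie-corrected pair-statistic AUC (asserted equal to the
  trapezoidal area), Hanley–McNeil intervals, Youden midpoint cut-offs,
  exact Clopper–Pearson intervals, exact Mann–Whitney for small untied
  samples.
* **Cost model.** Probe-first triage beats sequencing-only exactly when the
  sequencing:FACS cost ratio exceeds r\* = 1 / P(FACS positive);
  with perfect specificity r\* = 1/(π·s).

## Worked example

Simulate a mutant-dominant specimen (four-tube panel, 10^4 events per tube)
and quantify it:

```r
library(activeEGFR)
panel <- preset_panel("mutant_high", seed = 42, n_events = 10000)
quantify(panel)
#> Labeling result for 'mutant_high'
#>   corrected: EGFR(+) 0.10%, HX103(+) 99.74%, EGFR(+)HX103(+) 99.16%
#>   probe MFI: stained 892.2, DMSO 49.7, blocked 105.3
#>   blocking ratio: 0.934 (specificity pass)
```

The corrected EGFR(+)HX103(+) of 99.2% says essentially every gated tumour
cell carries probe-bindable (active) EGFR, matching the simulated truth
(95% of receptors active in 85% of events, the rest leukocytes and debris);
the blocking ratio of 0.93 means gefitinib preincubation removes 93% of the
specific probe signal, passing the binding-specificity check. The corrected
EGFR(+) is near zero by construction on simulated panels, because the DMSO
control tube carries the same antibody staining as the stained tube (see the
vignette).

Clinical performance recomputes from the packaged tables:

```r
rep <- reproduce()
rep$checklist[c(1, 7, 9, 16, 33), ]
#>                    quantity computed printed    tol pass
#> 1   auc_surgical_double_pos  0.85000    0.85 0.0051 TRUE
#> 7  sens_surgical_double_pos 83.33333   83.30 0.1000 TRUE
#> 9   acc_surgical_double_pos 82.60870   82.60 0.1000 TRUE
#> 16    auc_biopsy_double_pos  0.93000    0.93 0.0051 TRUE
#> 33         breakeven_prev50  3.00000    3.00 0.3100 TRUE
```

Row by row: the double-positive percentage discriminates activating
mutations with AUC 0.85 in surgical specimens (sensitivity 83.3%, accuracy
82.6% at the 30.1% threshold), AUC 0.93 in biopsies, and the probe-first
testing strategy breaks even when sequencing costs about 3× more than the
FACS assay at 50% mutation prevalence.

## Layout

* `R/binding.R` -- occupancy isotherm, turn-on brightness, titration fits
* `R/synthetic.R` -- seeded four-tube specimen simulator with truth labels
* `R/gating.R` -- gate configuration, threshold derivation, quantification
* `R/diagnostics.R` -- ROC/AUC, Youden, Clopper–Pearson, Mann–Whitney
* `R/cost.R` -- triage cost model and break-even sweeps
* `R/datasets.R` -- packaged cohort tables, loaders, summary validator
* `R/pipeline.R` -- stage wrappers and the reproduction checklist
* `vignettes/active-egfr-quantification.Rmd` -- methods and design notes
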