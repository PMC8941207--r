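# betaflux

Steady-state ¹³C metabolic flux analysis (MFA) for insulin-secreting
β-cells, with companion estimators for extracellular exchange rates,
futile glucose cycling, and compartmental redox state.

Pancreatic β-cells couple glucose catabolism to insulin secretion, and the
glucose-6-phosphatase catalytic subunit G6PC2 opposes glucokinase by
dephosphorylating glucose-6-phosphate back to glucose — a futile cycle that
dampens glycolytic flux. Quantifying how a perturbation such as loss of
G6PC2 reroutes glycolysis, the pentose phosphate pathway, the citric acid
cycle and anaplerosis requires fitting an atom-resolved network model to
isotope labeling data. This package provides that machinery to researchers
analyzing parallel-tracer GC-MS experiments ([1,2-¹³C₂]glucose and
[U-¹³C₅]glutamine) in β-cell lines, together with a synthetic-data
generator so every stage can be validated end to end without instrument
data.

## What it computes

* **Labeling simulation.** Atom-mapped reaction networks are decomposed
  into elementary metabolite units (EMUs); steady-state mass isotopomer
  distributions (MIDs) solve one linear system per EMU size. Rotationally
  symmetric pools (succinate, fumarate) are scrambled 50/50; measured
  fragment ions are convolved with the natural-abundance distribution of
  their derivative atoms (Mox-TBDMS, DiO).
* **Flux regression.** Fluxes v (net in the null space of the balanced
  stoichiometry S, plus nonnegative exchange fluxes for reversible
  reactions) minimize the variance-weighted sum of squared residuals

      SSR(v) = Σᵢ ( (mᵢ(v) − m̂ᵢ) / σᵢ )²

  over both tracers' fragment MIDs and the extracellular rates, restarted
  from ≥25 randomized initial guesses. Measurement σᵢ is
  max(control RMSD, replicate SEM). Goodness-of-fit is a two-sided χ² test
  on the SSR; per-flux 95% confidence intervals come from
  profile-likelihood continuation (SSR_min + 3.84).
* **Exchange rates.** Cell-specific uptake/excretion rates q
  (nmol/10⁶ cells/h; excretion positive) are the slope of the
  degradation-corrected extracellular amount against the integrated viable
  cell density, with first-order glutamine decay (k = 0.0031 h⁻¹ in
  cell-free controls).
* **Glucose cycling.** In a [1,2,3,4,5,6,6-²H₇]glucose experiment,
  recycled glucose reappears as the M+6 species (the C2 deuterium is lost
  at phosphoglucose isomerase). `cycling_rates()` estimates V_release,
  V_total uptake and cycling % = 100·V_release/V_total.
* **Redox panel.** Cytosolic NADH/NAD⁺, cytosolic NADPH/NADP⁺ and
  mitochondrial NADPH/NADP⁺ from lactate/pyruvate, malate/pyruvate/CO₂ and
  glutamate/α-ketoglutarate/NH₄⁺ pools via the LDH, MDH and GDH
  equilibrium relations (K_LDH = 1.11×10⁻⁴, K_MDH = 34.4×10³ μM,
  K_GDH = 2.49×10⁻³ mM).

## Worked example

Fit the bundled reduced core network (lumped glycolysis + citric acid
cycle + glutamine anaplerosis) to a synthetic noisy two-tracer dataset:

```r
library(betaflux)
net  <- core_network()
frg  <- core_fragments()
emus <- emu_decompose(net, frg)
# ... build a measurement_set `ms` (see vignette), then:
fit <- fit_fluxes(net, frg, ms,
                  tracers = list(glc = tracer_spec("Glc.ext", c(1, 2)),
                                 gln = tracer_spec("Gln.ext", 1:5)),
                  n_starts = 25, seed = 1)
print(fit)
```

```
13C-MFA flux fit
  SSR 52.758 on 46 degrees of freedom (chi-square 95% interval [29.2, 66.6]: accepted)
  15 net fluxes, 3 exchange fluxes; best of 25 restarts (seed 1)
  net fluxes (nmol/10^6 cells/h):
   GLY    LDH   LACR   PYRR    PDH     PC     CS    IDH  AKGDH    SDH    MDH
30.226 46.010 46.010  2.838 13.468  4.776 13.468 11.487 15.332 15.332  8.692
    ME   GLNU    GDH   CITR
 6.639  3.845  3.845  1.981
  exchange fluxes:
  IDH   MDH   GDH
5.855 7.957 9.686
```

The SSR of 52.8 lies inside the central 95% χ² interval for 46 degrees of
freedom, so the fit is statistically acceptable; the fitted glucose uptake
(GLY ≈ 30) and citrate synthase flux (CS ≈ 13.5) recover the generating
truth (30 and 14). Profile-likelihood intervals and normalized fluxes:

```r
confidence_intervals(fit, "CS")        # V_CS 95% CI: [12.51, 14.43]
normalize_fluxes(fit, "GLY")           # fluxes per unit net glucose uptake
```

A wild-type-like cycling experiment at 5 mM glucose (10% true recycling):

```r
wt5 <- make_ground_truth("WT", 5)
cycling_rates(simulate_cycling(wt5$cycling_percent, wt5$cycling_v_total))
```

```
Glucose cycling over 24 h:
  V_release          9.921 nmol/10^6 cells/h
  V_net_uptake      89.998 nmol/10^6 cells/h
  V_total_uptake    99.918 nmol/10^6 cells/h
  cycling             9.93 %
```

The estimator reads back 9.93% against a 10% ground truth. See
`vignettes/betacell-flux-analysis.Rmd` for the full model description and
the end-to-end pipeline (`run_pipeline()`).

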