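---
title: "Steady-state 13C flux analysis of beta-cell metabolism with betaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state 13C flux analysis of beta-cell metabolism with betaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaflux)
```

## The model

`betaflux` estimates intracellular reaction rates in insulin-secreting
β-cells from isotope labeling measurements at metabolic and isotopic
steady state. The model is an atom-mapped reaction network: each reaction
carries a letter code mapping every reactant carbon to a product carbon,
e.g. citrate synthase

```
CS: OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)
```

Two fixed assumptions follow the standard β-cell treatment. First,
citrate and isocitrate are one pool (aconitase rearranges no carbons), and
isocitrate dehydrogenase (IDH) is a single lumped reaction — cytosolic and
mitochondrial isoforms share carbon transitions and cannot be separated by
¹³C data. We number citrate so that the carboxyl cleaved by IDH is C6,
which encodes the two constraints that matter for the labeling
diagnostics: the IDH-released CO₂ derives from oxaloacetate C1, and
α-ketoglutarate C4–C5 derive from acetyl-CoA. Second, CO₂ is by default an
*unbalanced* pool at natural abundance: the intracellular bicarbonate pool
is large and exchanges with the medium, so refixation by pyruvate
carboxylase draws essentially unlabeled carbon. (Passing
`unbalanced = character(0)` to `read_network()` balances CO₂ explicitly;
the network must then contain a CO₂ release reaction.)

The bundled `beta_cell_network()` covers glycolysis, the oxidative
pentose phosphate pathway with transketolase/transaldolase return, the
serine/glycine branch, glycerol release via glycerol-3-phosphate
phosphatase, the pyruvate node (LDH, ALT, PDH, pyruvate carboxylase,
malic enzyme), the citric acid cycle with reversible IDH, and glutamine
anaplerosis. The glucose-entry flux `GK` is the *net* glucokinase flux:
glucokinase minus glucose-6-phosphatase. These two enzymes are not
separately identifiable from ¹³C data, which is why futile cycling has
its own deuterated-glucose assay (below). The serine branch is modeled
as net 3-phosphoglycerate → serine with downstream glycine/one-carbon
release; its published direction is ambiguous, and this choice keeps the
branch observable from the serine and glycine fragments. Succinate and
fumarate are rotationally symmetric: on production their label is
scrambled 50/50 between the two orientations, which the simulator
implements by averaging both atom-map orientations with half weight.
Atom maps for reactions whose published network is not reproduced in
print are the canonical textbook transitions; they reproduce every
qualitative diagnostic the data afford (pyruvate M+2 from
[1,2-¹³C₂]glucose, lactate M+1 via the oxidative PPP, citrate M+4
oxidative vs M+5 reductive under [U-¹³C₅]glutamine).

## EMU simulation

Steady-state MIDs are computed by elementary metabolite unit (EMU)
decomposition: measured fragments are traced backward through the atom
maps to the minimal set of carbon subsets whose labeling must be known.
Balances within each EMU size are linear given all smaller sizes, so
simulation solves one dense linear system per size block. Substrate EMUs
come from the tracer definition: labeled positions carry the tracer
enrichment (default 0.99 per position), unlabeled skeleton positions carry
natural ¹³C (0.0107; set `nat13c = 0` for idealized textbook
distributions), and the medium pool is a molecule-level mixture of tracer
and natural material.

Two numerical conventions matter. Pools with zero total flux at a
candidate flux vector (for example the PPP intermediates when the PPP is
shut) have undefined labeling; their EMUs are dropped with `NA`, which is
harmless because their downstream consumption weight is also zero, and an
error naming the species is raised only if a *measured* fragment sits on
such a pool. Reversible reactions are expanded into forward/backward
one-way fluxes, `fwd = exch + max(net, 0)` and `bwd = exch + max(-net, 0)`.

The simulator is validated against an independent brute-force simulator
(in the test suite) that iterates full 2ⁿ isotopomer distributions to a
fixed point; on toy networks with condensation, cleavage, reversibility
and a symmetric pool the two agree to 10⁻⁹.

Measured ions are derivatized fragments, so measurement-space MIDs
convolve the skeleton MID with the natural-abundance distribution of the
derivative atoms (C/H/N/O/Si/P/S isotopes; ²⁹Si and ³⁰Si dominate for
TBDMS). The reported window defaults to skeleton carbons + 2 mass units,
and both simulated and measured MIDs are renormalized over that window.

## Flux regression

`fit_fluxes()` is the central model-fitting function and returns a
classed `mfa_fit` object with the usual methods (`print`, `summary`,
`coef`, `predict`, `residuals`, `confint`, `plot`). Net fluxes are
parameterized in the null space of the balanced stoichiometry
(`v = N u`), so every candidate is exactly mass-balanced; each reversible
reaction adds a nonnegative exchange flux optimized on the bounded
transform `t = x/(x + s)` ∈ [0, 0.99] with scale `s` (default one tenth of
the flux bound). Irreversibility and the flux bound (default 10× the
largest measured rate) are enforced by penalty residuals.

The objective is the variance-weighted SSR over both tracers' fragment
MIDs and the extracellular rates, fitted *jointly* — one flux vector, two
simulated measurement blocks. M+0 channels are excluded from the residual
(an MID sums to one, so M+0 carries no independent information), and the
degrees of freedom count only independent measurements minus free
parameters. Each MID channel's standard error is
`max(control RMSD, replicate SEM)` — the RMSD of unlabeled control samples
against the theoretical natural MID, or the biological-replicate SEM,
whichever is larger (`assemble_errors()`); a floor of 10⁻⁴ avoids infinite
weights.

Optimization uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with finite-difference Jacobians. The MFA
objective is multimodal, so fits restart from randomized initial guesses
— net-flux candidates drawn log-uniformly within the bounds and projected
into the null space — and the best feasible solution is kept; 25 restarts
is the recommended minimum and the restart log (start, SSR, convergence)
is retained in the result. A fixed seed makes the whole restart schedule
bit-reproducible.

Goodness-of-fit is a *two-sided* χ² test: the fit is accepted when the
SSR lies in the central 95% interval for its degrees of freedom, which
flags both lack-of-fit and overfitting (or inflated measurement errors).
Confidence intervals use profile-likelihood continuation: one flux is
stepped from its optimum (doubling steps, then bisection to ~1%), all
other parameters are re-optimized from warm starts, and the bound is
where the SSR exceeds its minimum by qchisq(0.95, 1) = 3.84. Bounds are
truncated at zero for irreversible net and exchange fluxes; a bound that
never materializes inside the search range is reported as ±∞ and flagged
— the expected outcome for structurally uninformed exchange fluxes.

`normalize_fluxes()` divides all fluxes by a reference flux (net glucose
uptake `GK`, or citrate synthase `CS` to express reductive IDH flux per
unit of cycle turning), and `citrate_m4_m5_ratio()` computes the
oxidative/reductive diagnostic ratio whose decrease tracks rising IDH
exchange.

## Extracellular rates

`specific_rate()` regresses the degradation-corrected extracellular
amount `A(t) = C·V + k_deg ∫ C·V dt` on the integrated viable cell
density `∫ X dt` from a log-linear growth fit; the slope is the
cell-specific rate in nmol/10⁶ cells/h, positive for excretion. The
integrated form is exact for exponential growth with a constant rate.
Glutamine decays spontaneously; `estimate_degradation()` recovers the
first-order constant from cell-free plates (the generator uses
0.0031 h⁻¹), and evaporation is an optional volume-loss rate, default 0
(measured negligible in such controls).

## Glucose cycling

Futile cycling is assayed separately with
[1,2,3,4,5,6,6-²H₇]glucose: glucose that enters the cell, equilibrates
through phosphoglucose isomerase (losing exactly the C2 deuterium to
water) and is dephosphorylated back to the medium appears as an M+6
species. The EMU core is deliberately ¹³C-only; the deuterium assay has
its own estimator. Operationally, *recycled glucose is the
baseline-corrected M+6 abundance* — lighter species are attributed to
tracer impurity and noise, since single-pass isomerase exchange is fast
relative to cycling. From the M+6 time course, `cycling_rates()`
estimates the release rate as the appearance rate of recycled material
normalized to integrated cell density, with a small fixed-point
correction for re-uptake of already-recycled glucose (second-order in the
cycled fraction, but worth ~2% accuracy at 24 h); total uptake is net
glucose disappearance plus release, and
`cycling % = 100 · V_release / V_total`. The estimator is exact to
within 0.5 percentage points on noise-free courses across 0–30% truths
and stays below 3% (95th percentile) for zero-cycling experiments at the
0.003 MID noise scale.

## The synthetic generator

`make_ground_truth()` fixes the study conditions; its defaults are not
tuning knobs. Wild-type fluxes at 5 mM glucose are round values on the
scale of the measured β-cell exchange rates (glucose uptake
60 nmol/10⁶ cells/h, lactate release 70, glutamine uptake 8, with small
serine/glycine/glycerol/malate/succinate/aspartate overflows), balanced
by construction; 11 mM doubles all rates, matching the observed
roughly-twofold scaling of exchange fluxes with glucose. The knockout
scenario multiplies glycolysis ×1.67, the citric acid cycle ×1.6,
glutamine entry ×1.78, pyruvate carboxylase ×2, malic enzyme ×2.2 and IDH
exchange ×2, then re-balances by least-squares projection onto the flux
solution space with the pyruvate-kinase ratio pinned at 1.67 — so the
headline contrasts are exact by construction. Knockouts have zero futile
cycling; wild-type cycling is 10% (5 mM) and 20% (11 mM) of total
phosphorylation, and the cycling-dish uptake (100 nmol/10⁶ cells/h at
5 mM; these dishes are seeded far denser than the rate dishes) is chosen
so a 10%-cycling course accumulates an 8–10% recycled fraction within
24 h.

`simulate_experiment()` emits the full bundle — 21 fragment MIDs per
tracer in triplicate, unlabeled controls, 13 extracellular rate time
courses at 0/12/24/48/72 h, the deuterated-glucose course, and a redox
pool panel — with truncated-Gaussian MID noise (sd 0.003 per channel,
renormalized so MIDs still sum to one), per-replicate rate noise (CV
0.1), and full seed determinism.

What the generator does *not* emulate: chromatographic peak integration
and its systematic biases, instrument drift, incomplete derivatization,
slow approach to isotopic steady state (courses are generated *at*
steady state; the 24 h tracer horizon is taken as settled), medium
evaporation, and biological covariance between replicates. Passing tests
therefore demonstrate the estimators are correct and calibrated under
the stated error model, not that real chromatograms are free of
systematic error.

## Validation experiments and problem sizes

The package validates the statistical machinery on a reduced core
network (lumped glycolysis, full citric acid cycle, glutamine entry; 15
reactions, 6 free net fluxes, 3 exchange fluxes, 6 skeleton fragments)
— small enough that a 50-replication calibration study with
profile-likelihood intervals runs in minutes while exercising every
structural feature (condensation, cleavage, symmetry, reversibility,
anaplerotic cycles). On this network, across 50 noisy replicate
datasets, the two-sided χ² test accepts ~95% of fits and
profile-likelihood CIs for the glucose, citrate synthase, glutamine and
PDH fluxes cover the truth at ≥90%; wild-type/knockout contrast fits
recover the ×1.67/×1.6 ratios within their propagated CIs. Calibration
fits warm-start at the truth plus randomized restarts — the full 25-start
global search is exercised separately on the noise-free recovery test,
where the best of 25 random restarts reaches SSR ≈ 0 and reproduces all
fluxes to 10⁻⁴ relative.

## Known limitations

* Compartmentation is lumped: one IDH, one pyruvate pool. Ratios that
  depend on cytosolic/mitochondrial partitioning inherit that
  simplification.
* The redox panel uses the near-equilibrium relations with the printed
  constants; dissolved CO₂ and NH₄⁺ are mandatory user inputs (no silent
  defaults), and the resulting ratios are only as meaningful as the
  equilibrium assumption.
* Exchange-flux magnitudes far above the measurement-informative range
  are reported with unbounded upper CIs rather than point estimates.
* Non-stationary (time-resolved) isotopomer dynamics are out of scope;
  all fitting assumes isotopic steady state.
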