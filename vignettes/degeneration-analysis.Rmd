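---
title: "Modelling and analysing degeneration of penicillin production in chemostat cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing degeneration of penicillin production in chemostat cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The phenomenon and the model

High-producing *Penicillium chrysogenum* strains lose most of their
penicillin-G productivity within a few hundred hours of carbon-limited
chemostat cultivation. Because PenG synthesis consumes both carbon and a
large amount of ATP, a cell that does not produce grows faster on the same
substrate; a small non-producing subpopulation present at inoculation will
therefore outgrow the producers under carbon limitation. `chemodegen`
implements this competition hypothesis as a mechanistic ODE model and all
the analysis steps used to confront it with fermentation data.

## State and kinetics

The broth state is (x_p, x_np, s, p, paa, ohpaa, toc, e): producer and
non-producer biomass (Cmol/L), ethanol (Cmol/L), PenG (mmol/L), PAA and
o-OH-PAA (mmol/L), a dissolved biomass-like lysis byproduct (Cmol/L), and
a relative pathway-enzyme level e in [0, 1]. For each subpopulation i:

* uptake: `q_s,i = q_s,max · s/(Ks + s)` (Monod),
* growth (Herbert–Pirt partition):
  `mu_i = Yxs_max · (q_s,i − m_s − Yps · q_p,i)`,
* production: `q_p = qp_cell_max · e` for the producer, 0 otherwise,
* enzyme: `de/dt = k_ind (1 − e) · [s < s_repr] − k_decay e` — synthesis
  only once residual ethanol falls below the catabolite-repression
  threshold, so no penicillin is made during the batch phase,
* PAA: demand-driven consumption `(q_p + side)·x_p` with
  `side = phi/(1 − phi) · q_p` routed to o-OH-PAA (phi = 0.10 of total
  PAA consumption by default).

Dilution terms `−D (c − c_feed)` act once the feed starts. CO2 evolution
follows from carbon conservation per strain and O2 uptake from electron
conservation (degrees of reduction: ethanol 6, biomass 4.2, PAA 4.5, PenG
4.625, o-OH-PAA 4.25 per Cmol), so a simulated dataset closes its carbon
and redox balances *by construction* — which is exactly what makes it a
useful fixture for the balance module.

The growth-rate gap between the strains,
`delta = Yxs_max · Yps · qp_cell_max · e`, is the selection coefficient:
the producer/non-producer odds decay as `exp(−delta·t)` once the enzyme
level has saturated. This closed form is used as an independent oracle in
the test suite.

## Parameters and calibration

The study prints the *observables* of the reference cultivation — batch
`mu_max = 0.088 1/h`, peak population `q_p = 0.52 mmol/Cmol/h` at 40–80 h
after feed start, a >10-fold decline in roughly 270–430 h, steady-state
biomass ≈ 3 g DW/L on a feed of 0.25 Cmol/L ethanol + 4 mM PAA at
D = 0.03 1/h — but not the underlying yield and maintenance constants.
The defaults are therefore calibrated once so the default scenario
reproduces those observables, and are versioned in the preset YAML files
(`inst/extdata/presets/`), not hard-coded:

| parameter | value | unit | rationale |
|---|---|---|---|
| Yxs_max | 0.6 | Cmol/Cmol | with m_s fixes both mu_max and 3 g DW/L |
| m_s | 0.0115 | Cmol/Cmol/h | substrate balance at D = 0.03 gives 2.94 g DW/L |
| Ks | 1e-3 | Cmol/L | sharp carbon limitation; residual ethanol ~1e-4 Cmol/L |
| qp_cell_max | 0.78 | mmol/Cmol/h | population peak 0.52 with f0 = 0.15 |
| Yps | 0.0321 | Cmol/mmol | delta ≈ 0.015 1/h at peak; 10-fold decline at ~330 h |
| k_ind | 0.03 | 1/h | q_p peak at ~75 h after feed start |
| f0 | 0.15 | — | non-producing fraction that reproduces the decline timeline |
| gdw_per_cmol | 24.6 | g DW/Cmol | generic biomass CH1.8O0.5N0.2; the study states none |
| toc_fraction | 0.02 | — | "negligible (<10%)" byproduct formation; 2% chosen |

Yps = 0.0321 Cmol ethanol/mmol PenG lumps the 0.008 Cmol of ethanol-derived
carbon in the molecule with the ATP cost of synthesis and export. The
degeneration mechanism is a population shift (f0 > 0); a per-cell
enzyme-decay mode (k_decay > 0) is available because the underlying
mechanism is not settled, but it is off by default. The enzyme pool is a
deliberate single-state reduction of a published gene-regulation cascade:
the data constrain only repression in batch and a 40–80 h rise, which a
first-order pool reproduces.

Sub-cultivation presets (`sub-chemostat-4.1/4.2`) start from a degenerate
inoculum: f0 = 0.8 with the faster printed batch growth rates
(0.109/0.112 1/h). The true producer/non-producer split of a degenerated
culture is unknown; 0.8 encodes "mostly but not entirely non-producing",
consistent with the printed 2-fold production recovery on sub-cultivation.

## Numerical choices

`deSolve::lsodar` with rtol 1e-8 / atol 1e-10; the feed start ("just
before ethanol depletion") is located by a root at s = 1e-4 Cmol/L.
Dense output every 0.5 h. The fitting loop uses rtol 1e-6 and a 2-h grid —
a deliberate speed/accuracy trade-off that changes fitted fractions by
less than 1e-3. Integrator output is clipped of sub-atol negative
round-off. The algebraic `steady_state` solve is exact and is verified
against the integrator to 0.1% after 20 residence times.

# Synthetic measurements

`sample_timeseries` evaluates the trajectory every 12 h (a daily-ish
manual sampling rhythm; the study does not state its schedule) and applies
independent multiplicative Gaussian noise per observable, 3% by default,
truncated at zero. Truncation bias is negligible at 3% noise. The CSV
dialect is comma-separated with period decimals and `#`-prefixed metadata
lines (`# D_h-1=0.03`); decimal-comma files are rejected with a parse
error rather than silently misread. What the generator does *not* emulate:
autocorrelated sensor drift, volume changes from sampling, off-gas
analyser dynamics, and biological replicate-to-replicate shifts of the
degeneration onset — so passing tests demonstrate estimator correctness
under the stated noise model, not robustness to every artefact of real
fermentation data.

# Rate estimation

q_p(t) comes from the dynamic product mass balance
`q_p = (dC_p/dt + D·C_p)/C_x` with biomass converted to Cmol/L. Smooths
are global least-squares polynomials (default degree 5, on a centred and
scaled time axis) or a piecewise-cubic smoothing spline; derivatives are
always analytic derivatives of the smooth, never finite differences of
raw data. Rates are reported on the central 90% of the fit window to
avoid polynomial edge artefacts.

A global degree-5 polynomial resolves the peak well but cannot follow the
two-orders-of-magnitude decay into the tail, where its oscillating
residuals (~±0.05 mmol/L on a curve that has fallen to that size) can even
produce negative rate estimates. The decline metric `fold_decline`
therefore uses the spline smoother by default, while `qp_peak` keeps the
degree-5 polynomial. On noise-free reference data the spline-based
estimate tracks the simulator's internal q_p within 3% away from the
window edges.

Generations are doublings, `t·D/ln 2`: 500 h at D = 0.03 1/h is 21.6 ≈ 22
generations. The study's narrative uses this convention in one place and
an e-folding count (t·D = 15 ≈ "14 generations") in another for the same
~500 h; the package implements doublings throughout and flags the
discrepancy here rather than silently switching conventions.

# Balance closure

Recoveries integrate `D·(feed − broth)` flows plus the change in reactor
content over a window starting 2 residence times after feed start. The
degree-of-reduction convention (NH3-neutral N, +6 per S) is
`gamma = 4c + h − 2o − 3n + 6s` per Cmol; O2 counts 4 electrons per mol.
Compositions ship in `inst/extdata/compositions.tsv` (PenG C16H18N2O4S →
per-Cmol h = 1.125, o = 0.25, n = 0.125, s = 0.0625). The TOC byproduct's
composition is unknown in principle; it is assumed biomass-like, which is
consistent by construction here and flagged as an assumption for real
data.

The PAA recovery is reported per mol of *consumed* PAA (fates: PenG +
o-OH-PAA), not as a gross in/out ratio. Once production has declined,
most feed PAA passes through the reactor unconsumed; a gross ratio would
sit near 100% no matter what happened to the consumed part and would mask
a catabolic sink. On the consumed basis, a dataset with the o-OH-PAA
stream ignored closes at exactly 90%, matching the interpretation that a
90–110% closure rules out PAA catabolism.

# Metabolic flux analysis

The full published stoichiometric model of this strain is not reproduced;
the bundled network (`inst/extdata/network/`) is a reduced, fully
elementally balanced stand-in with 41 reactions and 34 balanced
metabolites: ethanol → acetaldehyde → acetate → acetyl-CoA, TCA cycle,
glyoxylate shunt, gluconeogenesis, a lumped oxidative pentose-phosphate
reaction supplying 12 NADPH per hexose, sulfate assimilation to cysteine,
valine and alpha-aminoadipate synthesis, ACV/IPN/PenG formation with PAA
activation, byproduct drains (o-OH-PAA, OPC, 6-APA, 8-HPA), a lumped
biomass equation whose precursor draw reproduces the biomass degree of
reduction of 4.2 exactly, ATP maintenance, and oxidative phosphorylation
with P/O = 1.5.

Cofactor conventions matter and are explicit: NADH/NADPH carry the
pseudo-formula H2 and the adenylates an empty formula, so every reaction
balances over C/H/O/N/S to 1e-9 while the cofactors stay exempt from
carbon and degree-of-reduction accounting; mitochondrial isocitrate
dehydrogenase is NAD-linked (fungal convention), making the
pentose-phosphate reaction the net NADPH source, which is why its flux
falls in the degenerated state. Flux conclusions that depend on these
specificities (notably the PPP contrast) should be read as conditional on
them.

The solver parameterises `N v = 0` exactly by an SVD null-space basis
(relative rank tolerance 1e-10) and fits the measured fluxes by
inverse-variance weighted least squares in that basis. Reversible
reactions are signed net fluxes; nothing is split. Overdetermined systems
report a weighted residual (the bundled scenarios are redundant in
exactly the carbon and electron closures of the measured set);
underdetermined systems list the non-estimable reactions instead of
pseudo-inverting. Measurement sets for the peak (t = 75 h) and
degenerated (t = 500 h) states are extracted from the simulation, with
trace byproduct secretion added as fixed fractions of q_p (OPC 8%, 6-APA
3%, 8-HPA 1%) and the gas rates recomputed from elemental closure so the
set is self-consistent. Because byproduct secretion scales with q_p here,
the cysteine-pathway flux contrast equals the q_p contrast (>10-fold);
the study's larger printed factor (~20-fold) requires byproduct rates
that fall faster than q_p, which are not printed — so only the >=10-fold
bound is asserted.

# Biosensors

The two sensor pairs (mannitol-6P/F6P, G3P/FBP) give relative NADH/NAD
ratios against a reference time point; equilibrium constants cancel in
the double ratio, which is scale- and unit-invariant and agrees across
pairs by construction. The energy charge uses Atkinson's formula
`(ATP + ADP/2)/(ATP + ADP + AMP)` — the study names but does not define
its index, so the standard definition is adopted and stated prominently.
Intracellular concentrations use the whole-cell 2.5 mL/g DW volume with
no compartment correction (the same simplification the study makes);
1 µmol/g DW ↔ 400 µM.

# Fitting f0

The objective is a weighted SSE between the observed q_p profile and the
simulated population q_p at the same times, with weights
`1/max(|q_p|, 0.1·max q_p)^2` — approximately relative error, floored so
the near-zero tail cannot dominate. A 0.01-step grid scan on [0, 0.5] is
refined by two-stage parabolic interpolation (a line search would chase
the faint numerical roughness of the simulated objective). The reported
95% interval is a sandwich (heteroscedasticity-robust, HC3-corrected)
standard error on the linearised profile with a t quantile. The profile
is visibly nonlinear in f0, so in well-specified simulation the interval
covers the truth somewhat below its nominal level — above 80% in the
shipped checks — and it does not account for smoothing bias when the
observed q_p comes from the estimation pipeline rather than direct
measurement. The selection strength is fixed from the producer's
burden parameters by default; freeing it together with f0 on short
profiles triggers an identifiability warning rather than a silent fit.

With the study's conditions (f0 = 0.15, 3% noise, 12-h sampling) the full
generate → estimate → fit pipeline recovers f0 with a median absolute
error well under 0.03 across noise seeds. The study's own printed value —
15% non-producers — rested on unpublished strain constants, so the
package asserts parameter *recovery* on synthetic data plus qualitative
agreement of the timeline, not the exact printed fraction.

# Problem sizes and limitations

The shipped analyses use one 680-h simulation (57 samples at 12-h
spacing), 25-seed Monte-Carlo replicates for recovery/coverage checks,
100 seeds for the noisy balance gate, and 20 random networks for the MFA
oracle — sizes chosen so the whole suite runs comfortably on a laptop
while keeping Monte-Carlo error well below the asserted tolerances.

Known limitations: no volume changes or pH/O2 control loops; no
compartmentation (peroxisomal transport is lumped into the pathway
reactions); PAA uptake is demand-driven rather than kinetic; the
enzyme-pool reduction cannot reproduce regulatory dynamics finer than its
single time constant; the MFA network is a documented stand-in, so its
absolute per-reaction fluxes are not comparable to the full published
model — only ratios and directions are; and the residual per-cell
productivity of a fully degenerated culture is unknown (the presets leave
a small producer remnant, consistent with the printed partial recovery on
sub-cultivation).
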