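---
title: "Modelling electroporation-mediated cisplatin uptake with poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electroporation-mediated cisplatin uptake with poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

## The problem

Electrochemotherapy potentiates a poorly permeant chemotherapeutic
(here cisplatin) by transiently permeabilizing the cell membrane with
high-intensity electric pulses. Clinically interesting pulse protocols range
over six orders of magnitude in pulse duration — single nanosecond pulses,
bursts of microsecond bipolar pulses, conventional 8 x 100 us monopolar
pulses, millisecond pulses — and a central practical question is whether
they are *equivalent*: does each protocol, at a suitably adjusted field
strength, deliver the same number of drug molecules into a cell?

`poreflux` implements a phenomenological, equivalent-circuit model of this
process for a spherical cell in a homogeneous field, plus the data
reduction used to confront it with ICP-MS uptake and clonogenic-survival
measurements. It predicts, for an arbitrary rectangular pulse train, the
number of cisplatin molecules internalized per cell a fixed time after
pulse delivery.

## The model

The membrane is an RC element charged by the applied field through the
conducting medium. Two pore states follow the induced transmembrane
voltage: a first state `N` permeable to small ions only, which can expand
into a second state `M` permeable to small molecules. Transport into the
cell is by diffusion only (no electrophoresis). With time normalized by the
membrane charging constant (`tau = t / tau_RC`) the system is

    dU/dtau = I_s - U (1 + gamma (N + M))
    dN/dtau = alpha U^2 - delta U^2 N - beta N + eta M
    dM/dtau = delta U^2 N - eta M
    dX/dtau = xi M (1 - X)

with the dimensionless source current `I_s = tau_RC sigma_ext h E0 / (U0
eps_m)` proportional to the applied field `E0`. `U` is interpreted here as
the induced transmembrane voltage normalized by the electroporation
threshold `U0`, which is what makes `I_s` dimensionless; the state
variables `N`, `M` and the normalized intracellular concentration
`X` (intracellular over extracellular) are dimensionless throughout.
Molecules per cell follow from `X` by

    count = X * X_e * (4/3) pi r^3 * N_A

with `X_e` the extracellular concentration and `r` the cell radius.

Because pore formation depends on `U^2`, reversing pulse polarity changes
nothing in `N`, `M`, `X` — bipolar protocols act through the same pathway
as monopolar ones. And because the transport equation never references
`X_e`, predicted molecule counts are *exactly* proportional to the
extracellular concentration: each protocol is integrated once and scaled.

### Parameters

Defaults in `model_parameters()` describe CHO cells with cisplatin as the
solute: threshold voltage `U0` = 258 mV, membrane thickness `h` = 5 nm,
cell radius `r` = 7.5 um, charging constant `tau_RC` = 1 us, membrane
permittivity 12 x 8.85e-12 F/m, solute radius 0.58 nm, defect radius
0.8 nm, cisplatin diffusivity 1.670e-9 m^2/s, rate constants
`alpha` = 2e-6, `beta` = 4e-8, `gamma` = 1e6, `delta` = 1e-3,
`eta` = 4e-9, permeability coefficient `xi` = 8.45e-4 (all per unit
normalized time), and medium conductivity 1.4 S/m (DMEM).

The permeability coefficient is linked to hindered diffusion through the
expanded defects by `xi = 3 H(lambda_m) D tau_RC / (r h)` where
`H` is the Renkin hindrance polynomial and `lambda_m` = 0.58/0.8 = 0.7250
the solute/defect radius ratio. Evaluating this with the default
parameters gives

```{r xi}
permeability_coefficient(model_parameters())
```

about 3.5% below the tabulated default constant 8.45e-4. The package keeps
the tabulated constant as the operative default — it is the value the
parameter set was calibrated with — and exposes the recomputation side by
side rather than silently substituting either for the other.

A related bookkeeping subtlety: for the 50 x 50 high-frequency protocol
the burst micro-structure (50 bipolar pulses of 2 + 2 us phases per burst)
gives 200 us of on-time per burst and hence 10 ms over 50 bursts. A total
on-time of 20 ms is sometimes quoted for this protocol; that figure is
inconsistent with the per-burst micro-structure and is not reproduced
here — `on_time()` reports the value implied by the waveform definition.

## Waveforms and the hybrid integrator

`pulse_train` objects are ordered piecewise-constant field segments;
constructors build monopolar trains and high-frequency bipolar bursts, and
five presets carry the study protocols at their per-protocol optimal
fields: `hf_50x50` (1.4 kV/cm), `mono_8x100us` (1.2 kV/cm), `mono_8x5ms`
(0.6 kV/cm), `ns_1x200` (12.6 kV/cm), `ns_25x400` (3.9 kV/cm at 10 Hz).
Burst spacing is start-to-start (`1/f`), trailing delays are trimmed, and
field lookup uses half-open `[start, end)` intervals so segment joins are
unambiguous.

Uptake is quantified 25 minutes after pulse delivery. In normalized time
that is a horizon of ~1.5e9 units, hopeless for direct fine stepping, but
almost all of it is field-free. The integrator is therefore hybrid:

* active segments and short gaps are integrated with an adaptive stiff
  solver (`deSolve`'s lsoda, analytic Jacobian), relative tolerance 1e-8,
  absolute 1e-12;
* a field-free interval longer than 100 `tau_RC` is integrated numerically
  only for its first 100 `tau_RC`, during which `U` discharges below 1e-6
  (its decay rate is at least 1 per unit of normalized time); `U` is then
  forced to 0 and the remaining pore relaxation and uptake advance with the
  exact closed-form solution of the linear field-free system
  (`relax_closed_form()`), including the degenerate `beta = eta` branch.

The default horizon is measured from the *end* of the train
(`t_end_reference = "train_end"`), matching samples processed a fixed time
after pulse delivery; this matters because `M` relaxes on a ~250 s scale
(`1/eta` in real time), the same scale as the 25-minute incubation.
`solver_config(method = "numeric")` disables the closed-form shortcut and
integrates everything with the stiff solver; the test suite uses it as a
brute-force cross-check at a 60 s horizon, where the two routes agree to
better than 1e-4 relative in final `X` on every preset (measured ~1e-7).
Halving both tolerances moves the final uptake by well under 0.1%.
Tolerance-level negative excursions of `N`, `M` (below 1e-9 in magnitude)
are clamped to zero so the trajectory invariants `N, M >= 0`,
`X` in `[0, 1]` hold exactly at every sample.

Trajectories are sampled at segment boundaries plus log-spaced points
inside long relaxation intervals — enough to plot the dynamics without
paying for uniform sampling across nine decades of time.

## The measurement pipeline

`run_protocol_grid()` produces the protocol x concentration prediction
grid (0/10/30/50 uM by default). On the measurement side,
`pt_mass_to_molecules()` converts ICP-MS picograms of platinum per cell to
molecules (1 mol Pt = 1 mol cisplatin, molar mass 195.084 g/mol, blank
subtraction floored at zero); `subtract_baseline()` removes the no-pulse
uptake at the matching concentration (replicates aggregated by arithmetic
mean, sample SD carried through, negative nets floored with a warning);
`model_vs_measurement()` forms per-condition model/measured ratios and a
per-protocol *geometric* mean across concentrations — ratios compose
multiplicatively, and no other aggregation is claimed to be the
experimental one. `survival_vs_molecules()` pairs uptake with clonogenic
survival on shared (protocol, concentration) keys.

## The synthetic-data generator

No measurement data are deposited with the study this package emulates, so
the pipeline ships a generator whose defaults are the study conditions:
4 replicates per condition, uptake at the 1e7 molecules-per-cell scale,
0/10/30/50 uM, ~100 cells plated per well in 3 wells, control plating
efficiency 0.8.

* **Uptake.** Replicate molecules are `distortion x truth x lognormal(mean
  1, cv 0.2) + baseline_slope x concentration`. Multiplicative lognormal
  noise reflects ICP-MS per-cell quantities being positive with roughly
  constant CV; 0.2 is a typical relative spread for 3-4 replicate
  experiments of this kind. The no-pulse baseline slope of 1e5 molecules
  per uM puts control uptake at 5e6 molecules at 50 uM — small relative to
  the electroporative signal, as observed. Control records carry the same
  multiplicative noise (a noise-free control would make replicates
  identical, which no real measurement is). Per-protocol `distortion`
  factors plant a systematic model/measurement disagreement for
  recovery testing.
* **Survival.** True survival follows a single-hit exponential link
  `S = exp(-k x molecules)` with default `k` = 1e-7 per molecule, which
  puts survival at the 50 uM grid points in the observed few-percent
  range. This link is an explicit artifact assumption — the underlying
  study reports the survival-uptake relation only graphically and asserts
  no functional form — and exists so that `fit_kill_rate()` has a ground
  truth to recover. Colony counts are binomial draws with `cells_plated`
  trials and success probability `pe0 x S`.

Both generators are fully deterministic under the configuration seed.
Round-trip tests recover planted distortion factors of 2.5 and 2 within
three standard errors at 1000 replicates, and the kill rate within 15% at
the default assay sizes (a design margin of ~3 sigma: the estimator's
spread across seeds is ~5%).

What passing these tests shows is that the *pipeline* is consistent — the
reductions invert the generative process. It does not validate the noise
model against real ICP-MS dispersion, nor the exponential survival link
against real clonogenic data; with real measurement tables only the
reduction functions are exercised, and the generator plays no role.

## Numerical and design choices

* Fields are stored in V/m internally; kV/cm appears only at interfaces
  (1 kV/cm = 1e5 V/m). Configuration keys carry explicit unit suffixes
  (`field_kV_per_cm`, `concentrations_uM`) because the protocols mix kV,
  V, ms, us and ns.
* Initial condition `U = N = M = X = 0`: intact membrane before pulsing.
* Avogadro constant 6.02214076e23 (exact); cell volume converted to litres
  inside `molecules_per_cell()` so concentrations are plain mol/L.
* The simulation horizon must cover the train; shorter horizons error
  rather than truncate.
* `fit_kill_rate()` uses unweighted least squares of `-log S` on molecules
  through the origin and a row bootstrap for its interval; points with
  zero observed survival (all colonies dead) carry infinite `-log S` and
  are excluded rather than imputed.
* Problem sizes in the shipped tests: full 25-minute horizons for all five
  presets (the high-frequency train has 9999 segments and dominates at
  about a minute of CPU), a 60 s horizon for the hybrid/brute-force
  cross-check, 1000 replicates for distortion recovery, and default assay
  sizes for the kill-rate round trip.

## Limitations

The model is deliberately non-spatial: one `U`, `N`, `M` per cell, no
angular dependence of the induced voltage, no pore-size distribution, no
electrophoretic contribution during pulses, no resealing heterogeneity
between cells. Its parameters were calibrated for CHO cells on propidium
iodide uptake and transferred to cisplatin by changing only the solute
radius, diffusivity and permeability coefficient; quantitative accuracy
beyond the order of magnitude should not be expected across very different
protocols, and the package's comparison tools exist precisely to measure
such over- or under-prediction per protocol. Whether the
nanosecond-protocol experiments used a different medium conductivity is
unknown; the presets assume 1.4 S/m throughout.
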