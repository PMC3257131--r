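---
title: "A compartmentalized model of cardiac energy transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmentalized model of cardiac energy transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckshuttle)
```

## The problem

In cardiac muscle the sites of ATP production (mitochondria) and ATP
consumption (myofibrillar actomyosin ATPase, ion pumps) are micrometres
apart, and a large body of tracer and kinetic evidence indicates that most
of the energy crossing that gap is carried not by ATP itself but by
phosphocreatine (PCr).  Mitochondrial creatine kinase (MtCK) in the
intermembrane space converts translocase-delivered ATP into PCr; PCr
diffuses to the myofibrils, where the cytosolic isoform (MM-CK) regenerates
ATP locally; creatine returns.  Two structural features make this shuttle
dominant: functional coupling of MtCK to the adenine nucleotide translocase
(ANT) through a local ATP microcompartment, and selective restriction of
the mitochondrial outer membrane (MOM, via VDAC within the Mitochondrial
Interactosome) to ATP and ADP but not to creatine, phosphocreatine or Pi.

`ckshuttle` implements a one-dimensional reaction–diffusion model of one
intracellular energetic unit and the analyses built on it: workload sweeps
of the working heart, the partition of mitochondrial energy export between
PCr and ATP under different structural assumptions, and the mitochondrial
response time `t_mito` after a step in demand.

## Model structure

The diffusion path of 1.3 µm is discretized into thirteen 0.1 µm units:
ten myofibrillar units, two cytosolic units and one intermembrane-space
(IMS) unit.  The MOM is a zero-volume interface between the last cytosolic
unit and the IMS (we interpret the three extra units this way because the
outer membrane carries no aqueous volume of its own; the choice is an
interpretation, not a measurement).  The mitochondrial matrix is one
well-mixed pool connected to the IMS by ANT, the Pi carrier and — via the
matrix reactions — ATP synthase.  Five species (ATP, ADP, PCr, Cr, Pi)
diffuse along the chain with no-flux boundaries at the myofibril core and
at the IMS/matrix boundary.

Extra-matrix water (0.3944 L/kg wet mass) is shared between the twelve
diffusive units in proportion to length, except for 5% assigned to the IMS
unit; matrix water is 0.1346 L/kg.  All whole-tissue fluxes are in
mmol s⁻¹ kg wet mass⁻¹ and the "idealized perfused heart" constants
(202.6 g dry weight/kg, 73 µmol/g dwt total creatine, 135 µmol/g dwt total
phosphate, 25 µmol/g dwt ATP+ADP) fix the conserved pools.  Total
phosphate is counted stoichiometrically (3 per ATP, 2 per ADP, 1 per PCr
and Pi), which every reaction in the network conserves exactly and which
leaves a physiological free-Pi pool of about 3 mM.

Contraction is a triangular ATPase pulse: a linear rise to the peak at
30 ms, a linear fall to zero at 60 ms, rest until the cycle ends at
180 ms; the pulse is scaled so its cycle mean equals the prescribed
workload.  Integration is explicit Euler at the reference step of 0.01 ms;
a cyclic steady state is declared when the end-diastolic state changes by
less than `steady_tol` (default 10⁻⁶ relative) between consecutive cycles.

## Rate laws and the choices behind them

**Creatine kinase.**  Every CK pool uses a reversible random-order bi-bi
law whose numerator vanishes exactly at the equilibrium mass-action ratio
[ATP][Cr]/([ADP][PCr]) = 166 and whose saturation limits obey the Haldane
relation.  The myofibrillar/cytosolic pool is parameterised by its
measured reverse (ATP-producing) activity — (1 − MtCK share) of the total
cellular 64 mmol s⁻¹ kg⁻¹ — with literature constants (MgATP 0.9,
Cr 15.5, MgADP 0.2, PCr 1.6 mM).  MtCK is parameterised by its forward
(PCr-producing) capacity equal to its activity share (20 mmol s⁻¹ kg⁻¹ at
the 31.25% fraction), in line with the experimental observation that the
maximal MtCK and ATP-synthase rates are equal; models that halve the MtCK
rate cannot sustain a dominant PCr flux.  The coupled, membrane-bound
octamer and the free enzyme differ kinetically: the coupled state uses the
channeled MgATP constant 0.016 mM with weaker Cr/PCr product handling
(Kb 2.5, Kd 15 mM), the free enzyme the in-vivo apparent MgATP constant
2.04 mM with Kb 5.2, Kd 0.45 mM.

**Microcompartment coupling.**  With coupling enabled the ATP seen by MtCK
is the bulk IMS value plus `gain · J²/(J + J_half)` where `J` is the
instantaneous ANT flux (gain 15 mM per flux unit, J_half 15).  Two
properties motivated the flux-saturating form over a simple proportional
one: accumulation must be strong during the systolic turnover burst — or
ADP flooding the IMS through an open outer membrane would transiently
reverse MtCK and destroy the coupled export advantage — yet near-negligible
at diastolic turnover, or the coupled system's resting PCr/Cr would sit far
above the uncoupled variants, which contradicts the near-equality of the
diastolic ratios across configurations.  The channeled MtCK flux is
additionally capped at 95% of the instantaneous ANT flux: the
microcompartment cannot transphosphorylate more ATP than the translocase
delivers to it.

**ATP synthase, ANT and the Pi carrier.**  The synthase is a product of
hyperbolic ADP and Pi terms (K_ADP 0.02 mM, K_Pi 1.0 mM) with a calibrated
maximal rate held in excess of the maximal demand, so respiration is
demand-limited — doubling the synthase capacity leaves VO₂ unchanged.  The
translocase is saturable in matrix ATP and IMS ADP and is opposed by the
cytosolic-side phosphorylation potential through a factor
`ADP/(ADP + q·ATP)` (q = 0.008).  This back-pressure term is the model's
stand-in for the thermodynamic (membrane-potential-dependent) control of
oxidative phosphorylation: it makes respiration respond supra-linearly to
cytosolic ADP near rest and progressively less steeply toward the maximal
workload, which is exactly the shape required by the observed fall of the
diastolic PCr/Cr ratio from 2.64 to 1.82 between the 0.400 and 0.678
workloads (a plain hyperbolic carrier cannot produce a flux ratio of 1.70
from an ADP ratio of 1.45).  The Pi carrier is a reversible saturable
exchanger, `V·(Pi_IMS − Pi_matrix)/(K + Pi_IMS + Pi_matrix)`; a one-way
uptake would pump the entire cytosolic Pi pool into the matrix.

**Transport.**  Cr, PCr and Pi diffuse at free-solution-like coefficients
(2.3–3.0 × 10⁻⁶ cm²/s).  The adenine nucleotides are assigned a reduced
apparent diffusivity of 8 × 10⁻⁷ cm²/s, reflecting their partial binding
to macromolecular complexes in the myofibrillar lattice.  This asymmetry
matters: with equal mobilities the myofibrils draw ATP directly whenever
the outer membrane is open and the shuttle loses its spatial advantage.
The MOM permeability is `coeff × PS_base` with PS_base = 12000 s⁻¹
(normalised to IMS volume, so the unrestricted conductance is far above
any demand) and the restriction coefficient 0.007 (severe), 0.1 (weak) or
1.0 applied to ATP and ADP only.

## Configurations

`config_preset()` encodes the structural variants: the `complete` system
(coupling on, severe restriction, MtCK 31.25%), a CK-free system, free
uncoupled CK without restriction, coupled CK without restriction,
`system_A` (no coupling, MtCK reduced to 8%, severe restriction), the
no-coupling/weak-restriction variant, and the latter with 1.7-fold reduced
adenine-nucleotide/creatine pools and 2.6-fold reduced Pi.

## Calibration

Two anchors fix the supply side, per `calibrate()`: oxygen uptake at the
maximal workload (3.52 mmol s⁻¹ kg⁻¹ ↔ ~174 µmol O₂ min⁻¹ g dwt⁻¹ at
ATP/O₂ = 6 — automatic at any converged steady state, verified to 2%) and
the diastolic myoplasmic PCr/Cr ratio of 2.64 at the 0.400 workload
(matched to 10% through the translocase capacity).  The diastolic ratio is
nearly flat in `ant_vmax` over a wide plateau — the coupled MtCK loop
buffers it — so `calibrate()` verifies the packaged capacity first and
only searches when the anchor is missed.  The remaining kinetic constants
above were fixed once against the published export partitions and
response times of the structural variants and are not re-fitted at run
time.

## What the analyses compute

`run_to_cyclic_steady_state()` integrates to a cyclic steady state and
records one full cycle; `summarize_cycle()` integrates the net MOM
effluxes of PCr and ATP over that cycle and reports the export partition
(storage drift, below 1% of the synthase flux at steady state, is excluded
from the denominator).  `run_transition()` applies a workload step at
end-diastole and fits `VO2(t) = V_after − (V_after − V_before)·e^{−t/τ}`
with both asymptotes free (profiled linear least squares over τ).
`exp_williamson_sweep()`, `exp_config_compare()` and
`exp_transition_table()` assemble the workload sweep, the four-variant
export comparison (run at 2.25 mmol s⁻¹ kg⁻¹; the comparison is defined
at "a high workload" and we fix it once below the maximal load) and the
transition table.

A short demonstration at reduced precision:

```{r demo, eval = FALSE}
params <- calibrate()
run <- run_to_cyclic_steady_state(
  initial_state(), config_preset("complete"),
  workload_protocol(3.52), sim_settings(steady_tol = 1e-5), params)
run$summary
```

## Synthetic data

`generate_working_heart_dataset()` emulates a Frank–Starling working-heart
experiment: oxygen uptake linear in workload (spanning ~20–174
µmol O₂ min⁻¹ g dwt⁻¹ over 0.4–3.52 mmol s⁻¹ kg⁻¹, the physiological
range) with multiplicative Gaussian noise, and a monotone-decreasing
PCr/Cr curve.  `generate_step_response()` produces mono-exponential
oxygen-uptake steps with known τ for testing the fitting stage.  These
generators are pure functions of their specification (including the seed).
They emulate the *shape* of real working-heart data, not its full error
structure — no inter-heart variability, no drift, no correlated NMR
noise — so passing tests demonstrate correctness of the analysis stages,
not robustness to every experimental artefact.

## Numerical choices

Explicit Euler at 0.01 ms is comfortably inside the diffusion stability
bound (`dt < dx²/2D ≈ 0.017 ms` for the fastest species) and halving the
step changes cycle-mean fluxes by well under 0.1%.  Concentrations are
clamped at −10⁻⁹ mM (accumulated rounding) and anything more negative
aborts the run naming the species and unit.  Convergence is declared on
the maximum relative end-diastolic change per species per unit; workload
steps are applied at a cycle boundary since diastole is the natural
reference phase.  The τ fit profiles the sum of squares over log-τ with
`optimize()`, solving the asymptotes by linear least squares at each
candidate; fits with R² < 0.95 carry a warning, flat series are an error.
Steady states for the reported analyses use `steady_tol = 10⁻⁵`; the
stricter default (10⁻⁶) changes the reported quantities only in the fourth
digit.

## Known limitations

* The model is 1-D and isothermal, with no pH, Mg²⁺ speciation, membrane
  potential, adenylate kinase or glycolytic phosphotransfer.
* With the outer membrane fully open and MtCK coupled, the simulated
  mitochondria pulse-follow the systolic ADP transient and the myofibrils
  draw a substantial share of ATP directly: this variant reaches a PCr
  export share of only ~35% per cycle rather than the ~72% reported for
  the source model, whose probability-formulation carrier kinetics are not
  reproducible from the published material.  The strict ordering of the
  four variants is unaffected.
* The oxygen-uptake response of the weak-restriction uncoupled variant has
  a sizeable instantaneous component (demand transients transmit through
  the weakly restricted membrane within a beat); the mono-exponential fit
  of the remainder then yields ~8 s rather than ~4.4 s, and the
  reduced-pool variant inherits the same bias (4.5 s vs 2.9 s).  The
  buffer-discharge energetics (deficit = τ·ΔJ ≈ ΔPCr) are nevertheless
  respected.
* System A's response time comes out ~20% faster than the published 8.7 s
  because its simulated diastolic PCr/Cr sits lower than the published
  pair, shrinking the discharged buffer.
* MM-CK is distributed uniformly over the myofibrillar and cytosolic
  units; any radial gradient of the enzyme is ignored.
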