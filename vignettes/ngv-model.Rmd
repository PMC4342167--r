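---
title: "The neuron-glia-vasculature metabolic model: equations, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neuron-glia-vasculature metabolic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngvmet)
```

## The model

`ngvmet` simulates activity-dependent energy metabolism in a small volume of
brain tissue represented by four compartments — a neuron (volume fraction
$V_n = 0.45$), an astrocyte ($V_g = 0.25$), extracellular space
($V_e = 0.2$) and a capillary ($V_{cap} = 0.0055$) — with the neuronal and
astrocytic compartments further split into cytosol and mitochondria
(mitochondrial fraction $\xi = 0.07$) to track NADH separately in each
sub-compartment. The state vector has 33 entries: intracellular sodium,
glucose, glyceraldehyde-3-phosphate, phosphoenolpyruvate, pyruvate, lactate,
cytosolic and mitochondrial NADH, ATP, phosphocreatine and oxygen per cell
type, capillary and extracellular metabolite pools, venous volume and
deoxyhemoglobin, and the Hodgkin-Huxley membrane variables
($\psi_n$, $h$, $n$) plus calcium.

Three modelling layers are joined by the electrogenic Na,K-ATPase, which
extrudes 3 Na$^+$ per ATP:

* **Excitability.** A single-compartment Hodgkin-Huxley neuron with
  instantaneous sodium activation ($m_\infty^3 h$), delayed-rectifier
  potassium, a high-threshold calcium current and a calcium-gated potassium
  current producing spike-frequency adaptation. The sodium reversal
  potential is recomputed continuously from intracellular sodium, and the
  leak reversal absorbs the baseline sodium and potassium leaks.
* **Metabolism.** Lumped glycolysis (an ATP-inhibited
  hexokinase–phosphofructokinase step with Hill inhibition
  $[1+(\mathrm{ATP}/K_I)^{n_H}]^{-1}$, phosphoglycerate kinase driven by
  cytosolic NAD$^+$, pyruvate kinase), near-equilibrium lactate
  dehydrogenase
  $J_{LDH} = k^+\,\mathrm{PYR}\,\mathrm{NADH} - k^-\,\mathrm{LAC}\,(N-\mathrm{NADH})$,
  a saturable TCA step producing 4 NADH per pyruvate, an electron-transport
  step consuming NADH (0.6 O$_2$ and 3.6 ATP per unit flux),
  malate–aspartate-type NADH shuttles between cytosol and mitochondria,
  creatine kinase as a rapid ATP buffer, and reversible facilitated-carrier
  transport of glucose and lactate between all compartments. ADP and AMP
  follow from the adenylate-kinase equilibrium
  $\mathrm{ADP}^2 = q_{AK}\,\mathrm{ATP}\,\mathrm{AMP}$ with a conserved
  adenine pool $A$; the ATP balance carries the usual
  $(1-\mathrm{dAMP/dATP})^{-1}$ correction.
* **Hemodynamics.** A venous-balloon model (volume $V_v$, deoxyhemoglobin
  $dHb$) fed by a prescribed arterial inflow $F_{in}(t)$, with the forward
  BOLD signal
  $\mathrm{BOLD} = V_{v,0}\left[(k_1+k_2)(1-dHb/dHb_0) - (k_2+k_3)(1-V_v/V_{v,0})\right]$.

The system is driven by a rate-coded presynaptic population: an excitatory
conductance $g_{exc}(t) = N_{exc}\,\bar g\,f_{exc}(t)$ activates AMPA
receptors on the neuron (current $I_{syn} = g_{exc}(E_{AMPA}-\psi_n)$,
about two thirds of which is sodium), while astrocytic glutamate uptake
co-transports 3 Na$^+$ per glutamate,
$J_{stim}^g = 3\Delta_{glut}N_{exc}f_{exc}(t)$. The presynaptic rate decays
exponentially from 3.2 Hz to 0.5 Hz with a 2.5 s time constant during
stimulation.

## Scenarios

`make_scenario()` builds the three canonical experiments:

* `in_vitro` — 20 s stimulation of a perfused slice: flow is constant and
  the capillary/vascular states (`O2_c`, `GLC_c`, `LAC_c`, `Vv`, `dHb`) are
  clamped at their resting values (their derivatives are zeroed, keeping one
  state layout for all scenarios).
* `in_vivo_rodent` — 60 s stimulation with functional hyperemia,
* `in_vivo_human` — 900 s stimulation with the same hyperemia shape; no
  separate human flow constants are established, so the human profile reuses
  the rodent shape with a configurable plateau (an explicit modelling
  choice, overridable through the scenario fields).

Functional hyperemia is a piecewise double exponential delayed by
$t_1 = 1$ s after stimulus onset,
$$F(t) = F_0\left\{1.1 + 1.5\left[e^{-(t-t_1)/5} - e^{-(t-t_1)/2}\right]\right\},$$
which steps to $1.1F_0$ at $t_1$ (the only discontinuity), peaks near
$+59\%$ about 3 s later, relaxes to a $+10\%$ plateau, and recovers to
baseline with a 5 s time constant after stimulation ends.

## Parameters

`ngv_params()` carries every constant in three groups (`param_groups()`):

* **fixed** — anatomy, physical constants, affinities, conductances;
* **optimized** — the 14 kinetic constants that shape the activity-evoked
  NADH transients (LDH forward rates, shuttle saturation constants, electron
  transport chain and TCA Michaelis constants, creatine kinase forward
  rates); these are the free parameters of `fit_free_parameters()`;
* **constrained** — 29 capacities that are functions of the others: each is
  solved by `steady_state_constrain()` so that the resting balance it
  appears in vanishes exactly at the imposed resting concentrations.

The constraint solve is sequential and local: creatine-kinase reverse rates
from the phosphocreatine equilibrium; PGK and PK rates from the GAP and PEP
balances; TCA capacity from the pyruvate balance; shuttle capacity from the
cytosolic NADH balance; electron-transport capacity from the mitochondrial
NADH balance; membrane oxygen permeabilities from the intracellular oxygen
balances; housekeeping ATPase loads from the ATP balances; glucose carrier
capacities from the neuronal, astrocytic and extracellular glucose balances;
and the lactate-to-capillary export capacity from the capillary lactate
balance. Three facts keep a handful of balances out of this scheme, and they
are worth stating because they shape what "residual zero by construction"
means:

* the four glucose balances are linearly dependent (their volume-weighted
  sum is total supply = total consumption), so only three carrier
  capacities are solvable; the small capillary-glucose residual is left to
  the fixed arterial supply;
* at the rounded resting concentrations the lactate gradients between
  cells and extracellular space vanish, making those carrier balances
  degenerate in their capacities (`Tmax_LAC_ne/ge/gc` are left at their
  published values);
* the sodium, deoxyhemoglobin and capillary-oxygen balances own no
  constrained parameter at all.

Consequently the exact model fixed point sits close to, but not exactly at,
the imposed resting concentrations; `find_steady_state()` locates it
properly (see below) and all relative observables are normalized to that
computed baseline.

## Numerics

The system is stiff: gating variables move on sub-millisecond timescales
while phosphocreatine and extracellular lactate relax over minutes. The
integrator is `deSolve`'s adaptive implicit `lsoda` with the right-hand side
compiled in C; an identical R transcription backs the steady-state solver
and the flux annotation of trajectories, and the two code paths are compared
to $10^{-10}$ relative on random states in the test suite.

* During the excitable epoch (stimulation onset up to 30 s) the step is
  capped at $2.5\times10^{-4}$ s and output is sampled every 0.5 ms so that
  every action potential is resolved; afterwards the cap is released to the
  slow metabolic timescale (1 s) and output thins to 0.1 s. The two-regime
  policy is a performance device, not part of the model, and halving the
  tolerances or the step cap changes the headline observables (NADH dip,
  lactate plateau) by well under 0.5% (tested).
* Default tolerances are `rtol = 1e-8` with a per-state absolute tolerance
  scaled to resting magnitudes; integration is deterministic, and two runs
  with identical inputs are bit-identical.
* Spikes are detected as upward crossings of $\psi_n$ through 0 mV with
  linear interpolation between samples.
* Removable singularities of the $\alpha_m$ and $\alpha_n$ rate functions
  (at $-33$ and $-34$ mV) are evaluated by their analytic limits within
  $10^{-6}$ mV of the singular voltage.
* The balloon outflow law is implicit in $dV_v/dt$; it is resolved
  algebraically before integration:
  $F_{out} = (F_0 v^{1/\alpha_v} + a F_{in})/(1+a)$ with
  $a = F_0\tau_v v^{-1/2}/V_{v,0}$, $v = V_v/V_{v,0}$.

`find_steady_state()` relaxes the quiescent system towards its attractor
(300 s by default, extended automatically when slow modes need it) and then
polishes with a damped Newton iteration using a central finite-difference
Jacobian with per-state relative steps. Newton works in logit-transformed
coordinates for the four NADH states, making the pool boundaries — where
the shuttle ratios diverge — unreachable. The Jacobian spectrum at the
solution (in physical coordinates) provides the stability verdict; marginal
spectra are flagged not stable by convention. With the published parameter
set the fixed point lands at $\psi_n = -73.5$ mV and extracellular glucose
2.480 mM, matching the imposed resting values within a fraction of a
percent, and is stable.

A genuine limitation surfaced by the well-posedness tests: if the total NAD
pool is doubled while keeping the published kinetics, the astrocytic
cytosolic redox state saturates at the pool boundary and GAP accumulates
without bound — no finite fixed point exists. The solver reports this as a
clear non-convergence rather than returning a spurious state; pools up to
about 1.5-fold retain a stable fixed point.

## Calibration

The free (optimized) parameters are fitted to relative-NADH target curves
from the 20 s in vitro protocol: a Nelder-Mead simplex minimizes the
unweighted sum of squared differences between the simulated and target
curves for the astrocytic cytosol, the neuronal mitochondria and the tissue
average, on a common 0.5 s grid (the weighting and grid are choices of this
package). Parameters are searched in log-space to enforce positivity; every
candidate first re-derives the constrained block and re-solves the steady
state, and failed candidates receive a large penalty. Convergence uses the
standard simplex coefficients with a $10^{-6}$ relative tolerance. A
self-consistency experiment in the test suite fits two strongly
identifiable constants (the electron-transport ADP affinities of both cell
types) from a 1.5-fold perturbed start against model-generated targets and
recovers them within 5% (in practice within 0.2%).

Reference curves may be supplied as CSV (`read_target_curves()`) or
generated synthetically. `generate_nadh_fixture()` produces curves with the
canonical evoked structure — a neuronal-mitochondrial dip of 10% at 5 s
with a small delayed overshoot, a monophasic astrocytic rise of 15%
starting about 8 s after onset, and a tissue curve mixing the two with
weights proportional to the resting NADH pools — as sums of exponentials
with optional seeded Gaussian noise. The fixture emulates the *shape* of
measured NADH fluorescence transients, not their noise structure, optical
depth weighting, or any hemodynamic contamination; a fit that recovers
parameters from the fixture therefore demonstrates the machinery, not the
biological accuracy of any particular parameter value.
`smooth_reference_curves()` implements the sums-of-exponentials smoothing
used to turn sampled points into continuous targets (multi-start
Levenberg-Marquardt, amplitudes initialized by linear least squares at
fixed decay constants).

## Observables

All derived read-outs are normalized to the computed steady state and
returned as tidy tibbles:

* tissue NADH mixes the four sub-compartments with weights
  $V_x(1-\xi)$ and $V_x\xi$; tissue lactate mixes neuron, astrocyte,
  extracellular space and capillary by their volume fractions; tissue
  ("intra-parenchymal") oxygen is the $V_n/V_g$-weighted mean of the two
  cellular oxygen states — the model has no extracellular oxygen state, and
  including the small capillary pool was evaluated and rejected because it
  dilutes the cellular transients that electrode measurements report;
* CMR$_{glc}$ is measured at the committed hexokinase–phosphofructokinase
  step (membrane transport is reversible in this model, so transport flux
  would not measure consumption); CMR$_{O_2} = 0.6\,(V_nJ_{mito,out}^n +
  V_gJ_{mito,out}^g)$; OGI is their ratio, flagged `NA` where CMR$_{glc}$
  vanishes;
* net lactate transports keep one sign convention throughout: flux from the
  first to the second compartment index is positive, so net neuronal import
  appears negative.

## What the simulations show

With the published parameter set, the in vitro 20 s stimulation produces
action potentials only within the first ~6 s (spike-frequency adaptation
plus the decaying input), a neuronal mitochondrial NADH dip of $-8\%$ at
~7 s with a small post-stimulus overshoot, an astrocytic cytosolic rise
that becomes substantial only ~10 s after onset and peaks near $+5\%$ at
~40 s, and tissue/extracellular lactate curves that superimpose to within
0.02 percentage points. The rodent 60 s scenario gives a tissue-oxygen dip
of $-2.4\%$ before the delayed flow rises, an overshoot of $+19\%$, and a
post-stimulus undershoot; the extracellular-to-capillary lactate export
peaks $+84\%$ above baseline after stimulation. The human 900 s scenario
yields a lactate dip followed by a $+68\%$ plateau, a $+36\%$ CMR$_{glc}$
increase that is mostly astrocytic, a $+5\%$ CMR$_{O_2}$ increase that is
mostly neuronal, a falling OGI, and a BOLD signal with a small initial dip.

One quantitative caveat deserves emphasis: the tissue-oxygen level late in
a sustained stimulation is a delicate balance between the $+10\%$ flow
plateau and the sustained sodium-load-driven rise in oxygen consumption
(about $+6\%$). These nearly cancel, so the sign and magnitude of the late
plateau (here about $-2\%$) are sensitive to small changes in the flow
plateau, the sustained presynaptic rate, or the pump kinetics, in a way the
larger transients (dip, overshoot) are not. The post-stimulus undershoot
inherits the same sensitivity through the recovery kinetics.

## Problem sizes and runtimes

The defaults used throughout the tests and the acceptance script are the
scenarios at their natural durations (20/60/900 s stimulations with 70–300 s
of recovery), 0.5 ms output sampling during the excitable epoch, and the
full 33-state system; a complete scenario integrates in a few seconds, and
the entire test suite (including the simplex recovery experiment and three
randomized-parameter draws) runs in well under a minute.

## Known limitations

* No glycogen pathway, pentose-phosphate branch, spatial diffusion, or
  pericyte/vasomotor signalling; the flow input is prescribed, not derived
  from a neurovascular cascade.
* The astrocytic membrane potential is a fixed parameter; astrocytic
  excitability and potassium dynamics are not modelled.
* Under sustained low-rate input the neuron rests a few millivolts below
  threshold and can emit rare isolated spikes late in very long
  stimulations; spike counts in that regime are marginal by construction.
* The parameter set is calibrated for the rounded published values;
  re-deriving the constrained block shifts some capacities from their
  published rounded values by up to tens of percent because several
  balances share residuals (documented above), without changing the fixed
  point they enforce.
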