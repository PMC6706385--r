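---
title: "Temperature-dependent gating of resurgent sodium currents: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent gating of resurgent sodium currents: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resurgentsim)
```

## The scientific problem

Inherited erythromelalgia (IEM) is caused by gain-of-function mutations
in the Nav1.7 sodium channel and presents with episodic burning pain
that is triggered by warmth and relieved by cooling. Steady-state
gain-of-function features of the mutant channels (hyperpolarized
activation, enlarged window currents) do not track temperature the way
the symptoms do. The quantity that does is the *relative resurgent
current*: the transient reopening current evoked on repolarization
after a strong depolarization, normalized to the transient current of
the same cell. This package implements a mechanistic model of that
phenomenon — a Markov gating model whose only systematic WT/IEM
difference in temperature sensitivity sits on the transitions that
generate the resurgent current — together with the voltage-clamp
protocols, curve analyses, synthetic-data generators and an axonal
excitability model needed to study its consequences.

## The gating model

### Rate law

Every transition rate is
$$k(V, T) = k_0 \, e^{k_1 V} \, Q_{10}^{(T - 25)/10},$$
with $k_0$ (ms$^{-1}$) the rate at 0 mV and 25 °C, $k_1$ (mV$^{-1}$)
the voltage dependence, and $Q_{10}$ the factor per 10 °C. The shipped
parameter sets (`channel_params("WT")`, `channel_params("IEM")`, also
as `inst/extdata/wt.yaml` / `iem.yaml`) differ in the speed of
activation/deactivation ($\alpha$: 100 vs 500 ms$^{-1}$; $\beta$: 0.55
vs 4 ms$^{-1}$), in the rates of the deep resurgent branch
(O$_2$I$_2$, I$_2$O$_2$, I$_1$I$_2$, I$_2$I$_1$), and — decisively —
in the temperature coefficient of the O$_2$$\leftrightarrow$I$_2$
transitions: $Q_{10} \approx 2$ in WT versus $\approx 3.3$ in IEM. In
transition-state terms a $Q_{10}$ of 3 versus 2 corresponds to a
barrier change of $\ln 3 \approx 1.1$ versus $\ln 2 \approx 0.69$ RT
per 10 °C step (`q10_activation_energy()`).

### State topology

The rate-law *names* (a single `c_on`/`c_off` pair for closed states,
`o_on`/`o_off` for the open state, no separate inactivated-row rates)
identify the scheme as a deactivation-coupled inactivation ladder: an
activation row C1–C4 (statistical multipliers 3:2:1 on
$\alpha/\beta$) opening through $\gamma/\delta$ into O1, a mirrored
inactivated row IC1–IC4–I1 connected by the same horizontal laws, and
vertical inactivation steps `c_on/c_off` at every closed state and
`o_on/o_off` at the open state. Because the open-state binding
equilibrium (`o_on/o_off` = 625) is vastly stronger than the
closed-state one (`c_on/c_off` = 0.2), a depolarized channel is
absorbed into I1, while recovery at hyperpolarized potentials proceeds
by deactivation *along the inactivated row* and unbinding at the
resting end — channels must deactivate to recover. The resurgent
branch hangs off the open states: O1⇄O2 (`o1o2/o2o1`), O2⇄I2
(`o2i2/i2o2`), I1⇄I2 (`i1i2/i2i1`); O1 and O2 conduct. A strong
depolarization drives occupancy through O2 into I2; on repolarization
that pool reopens through O2 before draining silently through I1,
producing the delayed inward hump.

We initially implemented the simpler topology in which a single I1 is
reached directly from both C4 and O1. With the published rates taken
verbatim this variant is untenable: the C4–O1–I1 triangle is
thermodynamically unbalanced by a factor of ~3×10⁴, which sustains a
standing open probability of ~0.17 at −40 mV (observed window products
are ~10⁻³), produces sustained/peak ratios of 15–20% (observed: a few
percent), and slows recovery from inactivation to ~12 ms at −80 mV
(model-calibrated values are 1–2 ms). The ladder transcription
resolves all three discrepancies without touching a single rate
constant, which is why it ships as the default
(`gating_scheme()`; the topology is data — an edge list serializable
to YAML — so alternative transcriptions are a one-file change).
Microscopic reversibility is *not* enforced anywhere: the rate table
is used verbatim and `cycle_imbalance()` reports the residual cycle
flux as a diagnostic.

The number of closed states (4) and the absence of extra allosteric
coupling factors on the inactivated row follow the principle of adding
nothing the rate table does not name; both are constructor arguments.

### Numerics

Occupancies evolve as $\dot p = p\,Q(V, T)$ with the generator
assembled by `build_generator()` (off-diagonals ≥ 0, rows sum to 0
within 10⁻¹²). Under piecewise-constant commands the propagation is by
matrix exponential per segment (`simulate_sweep()`), evaluated through
the eigendecomposition of $Q$ with a scaling-and-squaring Padé
fallback for ill-conditioned cases; the propagator is therefore exact
at the sample points up to linear-algebra round-off, and the stored
sampling interval only controls resolution (default 0.005 ms at
≥ 35 °C, where kinetics are 2–3× faster, and 0.01 ms otherwise).
Occupancy is checked to stay on the probability simplex within 10⁻⁶
(abort) and typically holds 10⁻⁹. The test suite and the acceptance
script verify the propagator against independent stiff-ODE integration
(`deSolve::lsoda`, rtol 10⁻¹⁰) to ≤ 10⁻⁶ maximum absolute occupancy
difference across reduced sweeps of all five protocol families, both
genotypes, at 15/25/40 °C. Initialization at a holding potential uses
the stationary distribution (`stationary_distribution()`, linear solve
with a long-time propagation fallback).

Currents are Ohmic, $I = g_{max} P_{open} (V - E_{Na})$ with
$E_{Na}$ = +100 mV; $g_{max}$ defaults to 1 because every reported
metric is a ratio.

## Protocols

`make_protocol()` encodes the standard whole-cell battery as data
(holding −120 mV throughout): activation I–V (−160…+40 mV in 5 mV
steps, 100 ms), steady-state inactivation (100 ms prepulse, default
−160…+20 mV in 10 mV steps, test +10 mV), resurgent (+40 mV × 10 ms
prepulse, repolarizations −20…−60 mV × 100 ms), paired-pulse recovery
(+20 mV × 10 ms pulses, gap at −80 mV growing in 0.1 ms increments),
and prepulse-duration (+60 mV prepulse of growing duration). The
inter-sweep interval (1.5 s) is modelled as full re-equilibration at
holding, an excellent approximation since all relaxation times at
−120 mV are far below 1.5 s. Two protocol parameters are not nailed
down by the source material and were fixed once: the inactivation
prepulse range (−160…+20 mV) and the resurgent repolarization duration
(100 ms, long enough for the slow decay at 15 °C). Analyses and the
acceptance script run the recovery protocol on a condensed gap grid
(~37 gaps spanning 0.2–120 ms) rather than the full 0.1 ms-increment
family: a mono-exponential fit is insensitive to the extra thousand
sweeps, and the condensed grid keeps a full temperature sweep within
minutes on one CPU.

## Analysis layer

All fits are deterministic and seed-free. The Boltzmann form is the
single signed-$k$ sigmoid $1/[1+\exp((V_h - V)/k)]$ for both curve
types (negative $k$ ⇒ descending inactivation curve, matching the
convention in which inactivation slope factors are reported negative).
Initialization: $V_h$ from the half-maximum crossing, $|k|$ from the
10–90% span divided by $\ln 81$; bounds $|V_h| \le 200$ mV,
$0.1 \le |k| \le 50$ mV; Levenberg–Marquardt least squares
(`minpack.lm`). The recovery fit is the offset-free rising exponential
$1 - e^{-t/\tau}$ through (0, 0) — a single time constant is reported —
with a one-parameter golden-section fallback when the Jacobian
degenerates on near-saturated data. Resurgent metrics locate the
delayed peak after the instantaneous tail has collapsed (first local
minimum of |I|), measure time-to-peak from the prepulse end, fit a
mono-exponential-with-offset decay from the peak to the sweep end, and
integrate resurgent charge from prepulse end to sweep end (window
chosen once; the source does not state integration bounds). Window
areas integrate the product of the two fitted curves by trapezoid on a
0.1 mV grid over [−120, +20] mV.

Model calibration honesty: the simulated WT relative resurgent current
at 25 °C is 0.077 at −20 mV, rising to ~0.15 at the maximizing
repolarization (−50 mV), against an experimental reference of
0.071 ± 0.003 whose repolarization-voltage convention is not stated.
The package reports the per-voltage table and its maximum rather than
tuning either.

## Synthetic data

`generate_noisy_sweeps()` adds Gaussian current noise (σ expressed as
a fraction of the transient peak, default 0.02 — chosen to mimic the
spread of small-n whole-cell data sets) and per-cell log-normal
conductance jitter (CV 10%, emulating cell-size variation) to simulated
sweeps; `generate_curve_dataset()` draws noisy samples of parametric
Boltzmann/recovery/prepulse-decay curves. A single master seed derives
per-replicate streams deterministically, so identical seeds give
identical datasets. What these generators emulate is additive recording
noise and scale variation only; they do not model leak, capacitive
transients, series-resistance error or TTX-subtraction artifacts, so
parameter-recovery results certify the fitting code, not robustness to
those experimental nuisances.

## The axon model

The excitability module is a Bostock-type space-clamped two-compartment
model: an excitable node coupled to the internodal membrane through the
Barrett–Barrett pathway. Nodal currents: transient Na split 73%
HH-type ($m^3h$) / 27% Markov model (the Nav1.7 share of axonal
transient Na conductance), first-order persistent Na, slow K, fast K,
leak, and a constant outward pump current (30 pA control, 15 pA IEM —
reduced local perfusion); internodal currents: fast K, HCN, leak. HH
gates use Boltzmann steady states and bell-shaped time constants
defined at 36 °C with a global $Q_{10}$ of 2.2; Markov rates use their
own per-transition laws. All membrane parameters live in
`axon_params()` and in the YAML scenarios
(`inst/extdata/control.yaml`, `iem_axon.yaml`).

Since the full published axon equations were not available, the
membrane parameterization is this package's own: conductances were set,
before any acceptance measurement, to give (i) a stable resting
potential near −81 mV, (ii) spike termination against the Markov
model's window current (this requires a large nodal fast-K conductance,
80 nS — the Markov scheme's steady open probability near −50 mV would
otherwise sustain a plateau), (iii) a classic recovery-cycle shape
(refractoriness → superexcitability → late subexcitability), and
(iv) visible sensitivity to the pump current (halving 30 → 15 pA
depolarizes rest by ~1.4 mV). Integration is fixed-step at
$dt = 10^{-3}$ ms: implicit Euler for the Markov block (the LU
factorization of $I - dt\,Q^T$ is cached while the nodal potential
moves < 10⁻⁶ mV; row sums of $Q$ being zero makes the step exactly
probability-conserving), semi-implicit Euler for gates and the 2×2
voltage system. Thresholds are found by bisection to 0.5% relative
tolerance with a spike criterion of the nodal potential crossing 0 mV
within 5 ms of test onset; the membrane state at test onset is computed
once per conditioning and reused across bisection iterations. A
conditioning waveform that fires the axon by itself yields a flagged
`NA` threshold rather than a number.

`run_net_battery()` mirrors the clinical TROND battery on reduced
grids chosen for tractability on a single CPU (5 stimulus widths, 12
electrotonus delays at ±20/±40%, 10 current-threshold levels, 17
recovery-cycle intervals; all exposed as arguments). Refractoriness is
read at 2.5 ms, or 3.2 ms below 30 °C, matching the convention used
when cooled axons are inexcitable at 2.5 ms.

## Known limitations and measured disagreements

* With the published rate table taken verbatim, every IEM $Q_{10}$ is
  ≥ its WT counterpart and IEM activation/deactivation are 5–7× faster.
  Consequently the mutant model's kinetics are *slower than WT when
  cold and faster when warm*. The simulated relative-resurgent
  enhancement correctly grows with temperature (mutant/WT ratio ~1.1 at
  15 °C → ~1.8 at 40 °C), but two directional features reported from
  experiments are reproduced with the opposite temperature ordering:
  the IEM-minus-WT time-to-peak difference shrinks rather than grows
  with warming, and IEM recovery from inactivation at −80 mV is faster,
  not slower, than WT. The corresponding checks in the acceptance suite
  fail and are left failing deliberately; the same reversal propagates
  to the axonal comparison, where the IEM-vs-control excitability
  signatures (raised refractoriness, raised SDTC, reduced late
  hyperpolarizing-electrotonus elevation, stronger inward
  rectification) emerge clearly at 25 °C but largely reverse at 36 °C.
* Simulated superexcitability is *larger* in the IEM scenario at both
  temperatures: the mutant's bigger resurgent current deepens the
  depolarizing afterpotential, and the 1.4 mV pump-mediated
  depolarization cannot override it. Raising the input resistance to
  amplify the pump effect produces afterdischarge bursting that breaks
  threshold tracking, so it was not done.
* The Markov scheme's steady-state activation and availability curves
  sit 10–25 mV hyperpolarized relative to fitted whole-cell curves;
  depolarizing threshold electrotonus therefore over-accommodates
  (TEd indices can be negative). Analyses that depend on the fitted
  Boltzmann layer use the published curve parameters, not the Markov
  steady states.
* Single-channel stochasticity, GHK permeation, ion accumulation,
  leak/capacitance artifacts and multi-node propagation are out of
  scope.

## Problem sizes used by tests and the acceptance script

Oracle-equivalence runs use reduced sweep subsets (2–3 sweeps per
protocol family) at a 0.25 ms sampling interval — the propagator is
exact per sample, so coarse sampling does not loosen the comparison.
Monte-Carlo recovery uses 100 replicates at σ = 0.02. The temperature
sweep uses the condensed recovery-gap grid described above. The NET
comparison runs the reduced battery grids at $dt = 10^{-3}$ ms for
2 scenarios × 2 temperatures.
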