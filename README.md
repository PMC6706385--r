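# resurgentsim

Markov-model simulation and kinetic analysis of resurgent sodium
currents in Nav1.7 channelopathy.

Inherited erythromelalgia (IEM) is an autosomal-dominant pain disorder
caused by gain-of-function mutations in the Nav1.7 sodium channel; its
hallmark is episodic burning pain triggered by warmth and relieved by
cooling. A candidate mechanism is the *resurgent* sodium current — a
transient inward current evoked on repolarization after a strong
depolarization, carried by channels that reopen through a second open
state (O2) instead of recovering silently — whose enhancement in the
mutant channel grows with temperature. `resurgentsim` provides, for
researchers in channel biophysics and axonal excitability:

* a **temperature-dependent Markov model** of wild-type and IEM-mutant
  Nav1.7 gating. Every transition rate follows
  `k(V,T) = k0 · exp(k1·V) · Q10^((T−25)/10)` (`k0` in ms⁻¹ at 0 mV and
  25 °C, `k1` in mV⁻¹). The state graph is a deactivation-coupled
  inactivation ladder (closed chain C1..C4 with an inactivated mirror
  row, open state O1) plus the resurgent branch O1⇄O2⇄I2⇄I1. The
  signature difference between genotypes is the temperature coefficient
  of the O2⇄I2 transitions: Q10 ≈ 2 (WT) versus ≈ 3.3 (IEM);
* a **voltage-clamp simulator** using the Q-matrix method
  (matrix-exponential propagation of the occupancy vector over
  piecewise-constant commands, Ohmic current with E_Na = +100 mV) and
  the standard protocol battery as data objects: activation I-V,
  steady-state inactivation, resurgent, paired-pulse recovery,
  prepulse-duration families;
* the **analysis layer** of whole-cell kinetics: Boltzmann fits
  `1/[1+exp((V_h−V)/k)]` with signed slope factor, I-V regression for
  V_Na and G_max, window-current products and areas, sustained/peak
  ratios, resurgent metrics (I_res/I_trans, charge ratio, time to peak,
  decay τ and its voltage regression `1/τ = A·exp(kV/25)`),
  mono-exponential recovery and prepulse-decay fits;
* a **seeded synthetic-data module** (Gaussian current noise, log-normal
  cell-size jitter) so every fitting stage is testable by parameter
  recovery;
* a **two-compartment myelinated-axon model** (node + internode,
  Barrett–Barrett coupled; 27% of nodal transient Na conductance
  replaced by the Markov model; constant pump current) with
  threshold-tracking simulation of the nerve-excitability-test (NET)
  battery: strength-duration, threshold electrotonus, current-threshold,
  recovery cycle.

## Worked example

Simulate the resurgent protocol for both genotypes at 25 °C and compare
the relative resurgent currents:

```r
library(resurgentsim)

scheme <- gating_scheme()
wt <- channel_params("WT")

## stationary occupancy at the holding potential, then one battery
traces <- run_battery(scheme, wt, make_protocol("resurgent"), T = 25)
ref <- run_battery(scheme, wt,
                   make_protocol("activation_iv", v_min = -20, v_max = -20),
                   T = 25)[[1]]
resurgent_metrics(traces, ref)
#> resurgent metrics:
#>  voltage  peak   ratio time_to_peak tau_decay charge_ratio monotone
#>      -20 5.029 0.07743         3.22     6.972        0.942    FALSE
#>      -30 6.558 0.10097         2.95     8.037        1.268    FALSE
#>      -40 8.311 0.12796         2.68     8.252        1.750    FALSE
#>      -50 9.487 0.14607         3.13     6.367        2.373    FALSE
#>      -60 7.679 0.11822         1.42     3.881        2.164    FALSE
```

The `ratio` column is the resurgent peak normalized to the transient
peak of the −20 mV activation sweep of the same simulated cell; it peaks
near −50 mV, with a delayed peak (`time_to_peak` > 0, measured from the
end of the +40 mV prepulse) and a slow decay — the defining shape of a
resurgent current. Running the same battery with
`channel_params("IEM")` and forming the mutant/WT ratio of these ratios
at 15, 25 and 40 °C shows the heat-dependent enhancement (about 1.2 at
15 °C rising to about 1.8 at 40 °C):

```r
cfg <- study_config(genotypes = c("WT", "IEM"), temperatures = c(15, 25, 40),
                    protocols = c("activation_iv", "resurgent"))
tab <- run_temperature_sweep(cfg)
subset(tab, metric == "ratio_to_wt")
#>  genotype temperature  protocol      metric    value units
#>       IEM          15 resurgent ratio_to_wt 1.233863 ratio
#>       IEM          25 resurgent ratio_to_wt 1.496409 ratio
#>       IEM          40 resurgent ratio_to_wt 1.844407 ratio
```

Fitting works the same way on simulated or synthetic data:

```r
v <- seq(-90, 30, 5)
ds <- generate_curve_dataset("boltzmann", list(vh = -21.8, k = 8.3), v,
                             noise_model(sigma = 0.02, seed = 1))
fit_boltzmann(ds$replicates[[1]]$x, ds$replicates[[1]]$y, "activation")
#> Boltzmann activation fit: Vh = -22.23 mV (se 0.22), k = 8.71 mV (se 0.2)
```

The axonal comparison (control = WT channels + 30 pA pump; IEM = mutant
channels + 15 pA pump, 36 °C and 25 °C) is one call:

```r
net <- run_net_comparison(study_config())   # threshold tracking; ~30 s
subset(net, metric %in% c("sdtc", "refractoriness", "superexcitability"))
```

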