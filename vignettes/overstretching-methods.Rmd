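---
title: "Thermodynamics and kinetics of the DNA B-to-S transition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics and kinetics of the DNA B-to-S transition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overstretch)
```

## The system and the measurement

A short DNA duplex (here 60 bp) held between two beads in an optical trap
and pulled through the 55-72 pN window hops reversibly between its
canonical B form and the overstretched, base-paired S form. On a recorded
force-distance curve each hop is an abrupt force drop (B-to-S) or rise
(S-to-B) of roughly `K_eff * dX ~ 1 pN`, where `K_eff ~ 0.1 pN/nm` is the
effective stiffness (dominated by the trap) and `dX ~ 9-11 nm` the length
the molecule gains in one jump. The trap moves at constant velocity, so
the force ramps at the loading rate `r = K_trap * v` (5 pN/s at the
default 50 nm/s). This package implements the full analysis of such
records and a kinetic Monte Carlo generator that emulates them, so that
every stage can be validated against known ground truth.

## The two-state model

Two states with extensions differing by `dX` at force `F` have occupancy

$$P_S(F) = \frac{1}{1 + e^{-\Delta X (F - F_{tr})/k_BT}},$$

with the transition force `F_tr` defined by equal occupancy. The hopping
rates follow the Bell-Evans form, pivoted at the crossing where both
equal `k_tr`:

$$k_{B\to S}(F) = k_{tr}\,e^{+(F-F_{tr})X_{B\to TS}/k_BT},\qquad
  k_{S\to B}(F) = k_{tr}\,e^{-(F-F_{tr})X_{S\to TS}/k_BT}.$$

Detailed balance requires `X_B->TS + X_S->TS = dX`; the constructor of
`construct_model()` enforces it. All energies use `kBT = 4.089 pN nm`
(23 C); 1 kBT is 0.59 kcal/mol.

### End fraying

Higher forces peel base pairs off the free duplex ends before the
cooperative transition, so the transition extension shrinks with force:
`dX(F) = dX_tr - fray_slope (F - F_tr)`, with `fray_slope = 1 nm/pN` as
the default. Dividing `dX` by the 0.23 nm/bp per-bp elongation known from
polymeric DNA overstretching gives the number of transitioning base pairs
`n`, and `g = G_BS/n` the per-bp transition free energy.

## The synthetic-data generator

`simulate_cycle()` integrates the two-state master equation by kinetic
Monte Carlo at a 0.1 ms substep (ten times the 1 kHz recording), with
switching probability `1 - exp(-k(F) dt)` per substep. Fraying is treated
as deterministic in force (it re-equilibrates much faster than the ramp),
which makes each state's force a fixed function of trap position: the B
branch is the ramp line, and the S branch satisfies
`F = F_line - K_eff dX(F)`, i.e. it is slightly steeper. A switch moves
the force from one branch to the other at fixed trap position. Every
switch is logged with its pre-jump force, landing force and the frayed
extension `dX(F)` at the moment of the jump; Gaussian force noise
(`sigma_F = 0.2 pN` by default -- the study never states its noise
amplitude, so this is a declared fixture choice) is added afterwards.

Defaults follow the experimental protocol: 55-72 pN window, 0.1 pN/nm
trap, 50 or 200 nm/s, 1 kHz sampling, cycles starting in B at the window
bottom. The hopping rate at the crossing is not a published number; each
named preset's `k_tr` was calibrated once, by simulation at the default
protocol, so that the generator's mean number of switches per
stretch/release cycle matches the published per-cycle transition count
(25 for the unmodified duplex, up to 65 for the triply modified one), and
then frozen. A force-clamp variant (`simulate_clamp()`) provides the
detailed-balance check: its long-run S occupancy converges to `P_S(F)`.

What the generator does *not* emulate: drift of the instrument between
cycles, bead-handle compliance beyond the constant `K_eff`, stochastic
fraying kinetics, and force-induced melting (a tether-loss channel is
deliberately out of scope). Passing tests therefore show that the
analysis chain is correct for an idealised, drift-free two-state record
-- not that it is robust to every artefact of real data.

## Detection

`detect_dataset()` segments the record at trap-position turning points,
fits the two elastic branches, and finds jumps as threshold crossings
(default 0.5 pN, about half the expected jump) of a 3-sample-spanned
difference of the median-filtered force (window 5). Candidates are
re-measured from the raw samples of the adjoining dwells -- selected by
nearest-branch classification on the filtered signal, then re-selected
symmetrically around the measured levels -- and confirmed only if the
settled step is at least two thirds of the local branch separation.
The branch lines are fitted once on the pooled trace (drift-free data;
`pool_branches = FALSE` restores per-half-cycle fits), with free slopes:
the S line is steeper than the B line by exactly the fray signal, so the
per-event extension change is read as the horizontal distance between the
fitted lines at the event force. This geometric readout is what makes
the extension-versus-force regression (the fraying slope) recoverable to
a few percent.

### Bandwidth, dead time, and what cannot be detected

At the calibrated hopping rates a sizeable fraction of dwells lasts less
than ~3 samples at 1 kHz; those switches are invisible to any detector at
this bandwidth, so the detected count per cycle is roughly 55-60% of the
generator's true count. Exact detector/generator closure is therefore
asserted on slow-hopping fixtures where every dwell is resolvable, and
the per-cycle counts reported by the pipeline are bandwidth-limited (the
count *ordering* across constructs, which carries the barrier signal, is
preserved). Three consequences are handled explicitly downstream:

1. **Risk-set conditioning.** Only dwells longer than the dead time are
   observable. Dwell durations are memoryless at fixed force, so
   excluding the first dead-time span of every observed dwell from the
   risk set keeps the hazard estimator unbiased under that conditioning.
2. **Dwell validity.** A same-direction succession of events means a
   switch was missed in between; the bracketed interval carries no
   residence information and is dropped, as are first/last dwells
   inconsistent with the known pure-B (window bottom) and pure-S (window
   top) states at the ramp ends.
3. **Partner censoring.** An event is only recorded if the dwell it
   lands in outlives the dead time, which attenuates the apparent rate
   by `exp(-tau k_partner(F_landing))` with `tau` = 3 samples (the
   detection span). The Bell-Evans fit inverts this attenuation
   iteratively using the opposite direction's fitted rate, trusting the
   correction only while it is below e^0.5 and dropping bins beyond.
   This calibration was validated against the generator: the measured
   attenuation follows the exponential model with `tau ~ 2-4 ms`.

## Equilibrium analysis

`estimate_ftr()` bins the per-sample state labels by force (0.25 pN),
fits the two-state occupancy with free midpoint and width, and bootstraps
over cycles (200 resamples, fixed stream) for the SEM -- cycles, not
events, are the independent units. The transition free energy is the
mean per-event jump work `F dX / kBT` at the pre-jump force, averaged
over both directions (hopping is near-equilibrium, so forward and
reverse works bracket the free energy tightly); the Bennett
acceptance-ratio estimator `bar_free_energy()` combines the two work
samples by solving the standard two-sided self-consistency equation by
root bracketing and, as expected, lands at or just below the mean work.
The number of transitioning base pairs, the per-bp free energy, the
stabilisation free energy of a modified duplex
(`dG = G_mod - n_mod g_ref`) and the fraying slope (OLS of per-event
extension on force) complete the table of equilibrium quantities.

## Kinetic analysis

Dwell intervals between detected events, left-truncated at their entry
forces and right-censored at the ramp ends, feed a product-limit survival
estimator (via the survival package) and a binned hazard reconstruction
`k(F) = r d / L` with `d` the exits and `L` the at-risk force length per
bin -- at-risk intervals are anchored at the well-measured exit force with
width set by the dwell *duration*, because differencing two noisy force
reads would inflate short dwells' intervals by the noise amplitude.
Weighted least squares of `ln k` on force within `F_tr ± 2 pN` gives the
two transition-state distances (slope times kBT), their crossing the
transition force and rate, and the zero-force intercepts -- reported as
extrapolations only, sixty piconewtons outside the data.

The per-bp barrier comes from count scaling: if the barrier free energy
is extensive in `n`, the hopping rate at the crossing (and hence the
per-cycle count `N` at fixed protocol) scales as `exp(-n g_TS)`;
regressing `ln N` on `n` across constructs gives `g_TS ~ 0.11 kBT/bp`,
and the attempt rate follows as `k0 = k(F_tr) e^{n g_TS}`.

## Free-energy profile

`build_profile_at_ftr()` draws the per-bp landscape at the transition
force: equal minima at the B (x = 0) and S (x = 0.23 nm/bp) extensions
with quadratic walls derived from the known stretch moduli (~1000 pN over
a 0.34 nm/bp rise for B, ~3000 pN over 0.58 nm/bp for S), joined to the
barrier top (height `g_TS`, position ~60% of the path) by cubic Hermite
bridges placed at the monotonicity boundary, so the curve is C1 and rises
monotonically from each well to a single maximum. The interpolant between
the anchored points is illustrative geometry; the quantitative content is
the barrier height and position and the endpoint values. Tilting by
`+F_tr x / kBT` gives the zero-force landscape; for every preset it rises
monotonically beyond the barrier with no local minimum near the S
extension -- the overstretched state is entirely force-induced. The
metastability classifier demands a local minimum within 10% of the S
extension with an escape barrier above 0.05 kBT/bp.

## Numerical choices and problem sizes

* Substep 0.1 ms; the generator refuses configurations whose hopping-window
  rates are not resolved (`k dt > 0.1`).
* Force bins 0.25 pN throughout; Bell-Evans window `F_tr ± 2 pN`; at
  least 4 rate bins and 5 events per bin.
* Occupancy bootstrap: 200 per-cycle resamples on a fixed stream.
* Bennett root solved to 1e-6 kBT with bracket expansion.
* Profile grid 0.001 nm/bp on `[0, 1.2 x_BS]`.
* The test suite exercises the full chain on a 176-cycle unmodified-duplex
  dataset (the published cycle count) plus smaller 10-60-cycle fixtures;
  this keeps the complete suite under a minute on one core while leaving
  recovery tolerances (0.2 pN on `F_tr`, 3% on `dX`, 15% on the
  transition-state distances, 0.15 nm/pN on the fraying slope) tight.

## Known limitations

* The recovered per-cycle counts and crossing rates are detection-limited
  (bandwidth); they are reported as observed, with the dead-time model
  above as the documented interpretation.
* The reverse transition-state distance is the noisiest recovered
  quantity (~10% seed-to-seed scatter at 176 cycles), because the
  force range where the reverse rate is both measurable and uncensored
  is narrow.
* The fraying slope recovered for the fastest-hopping presets (e.g. the
  triply modified duplex) is biased low: flicker censoring thins exactly
  the events that carry the force-extension signal.
* Branch pooling assumes a drift-free instrument; for drifting records
  use per-half-cycle fits and expect a weaker fray signal.
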