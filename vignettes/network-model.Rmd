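---
title: "A population-level model of the basal ganglia-thalamocortical network under DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-level model of the basal ganglia-thalamocortical network under DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dbsnet` simulates a Wilson-Cowan (mean-field firing-rate) model of the
combined cerebellar-basal-ganglia-thalamocortical circuit implicated in
movement disorders.  Seven neural populations are represented by the
fraction of their cells active per unit time: cortex (Cx), the
ventral-intermediate thalamic relay (Th), the thalamic reticular nucleus
(nRT), the deep cerebellar nuclei (DCN), the external and internal globus
pallidus (GPe, GPi), and the subthalamic nucleus (STN).  Cx, Th, DCN and
STN are excitatory; nRT, GPe and GPi inhibitory.  Each population obeys

$$\tau_i \frac{da_i}{dt} = -a_i + (k_{p(i)} - a_i)\,
  Z_{p(i)}\!\big(\textstyle\sum_j \pm w_{ij}\, a_j\big),$$

with $p(i) \in \{e, i\}$ the population's polarity, $k_p$ the activity
ceiling, and $Z_p$ a sigmoid response function pinned to $Z_p(0) = 0$:

$$Z_p(x) = \frac{1}{1+e^{-b_p(x-\theta_p)}} - \frac{1}{1+e^{b_p\theta_p}}.$$

The wiring follows the anatomy: Th drives Cx ($w_1$); Th is driven by Cx
($w_2$), DCN ($w_4$) and inhibited by nRT ($w_3$) and GPi ($w_5$); nRT is
driven by Cx ($w_6$); DCN receives only the constant ascending drive
`ext`; GPe is driven by STN ($w_7$) with self-inhibition ($w_8$); GPi by
STN ($w_9$); STN by Cx ($w_{10}$) with GPe inhibition ($w_{11}$).  Weights
are stored as non-negative magnitudes; the polarity of every connection is
fixed in the equations, and a loader handed signed weights refuses them
rather than guessing.

Because the DCN equation depends on nothing but `ext`, it decouples: its
activity converges to the closed form
$k_e Z_e(\mathrm{ext})/(1 + Z_e(\mathrm{ext}))$ (`dcn_equilibrium()`) and
acts purely as a constant ascending source into the thalamus.  This is a
tested invariant.

### Sigmoid constants

The defaults are the two classical Wilson-Cowan limit-cycle constant
pairs — slopes and thresholds $(b, \theta)$ of $(2.0,\ 3.7)$ and
$(1.3,\ 4.0)$ — with the first pair assigned to the excitatory response
$Z_e$ and the second to the inhibitory response $Z_i$, and ceilings equal
to their consistent values $1 - 1/(1+e^{b\theta})$ (0.9994 and 0.9945).
These constants are frequently quoted with the slope and threshold
symbols, or the e/i labels, interchanged; the four possible assignments
produce *qualitatively* different circuits.  We fixed the assignment by
the dynamics it must support: under the default assignment, and only
under it, the three reference parameter columns below produce the
gamma/tremor/beta regimes with the documented frequencies, amplitude
ordering, phase ordering, and the STN→GPe switching behaviour.  The other
three assignments either drive the network into a saturated stable fixed
point (no oscillation from any initial state in a 300-point scan of the
state box) or place the slow regime at roughly twice its documented rate.
The constructor checks (but does not enforce) ceiling/slope/threshold
consistency to 5e-4, so detuned variants remain expressible.

### Regime presets

Three named parameter columns (`wc_preset()`), all with `ext = 3.42` and
τ = 10 ms:

| weight | role | healthy | tremor | beta |
|---|---|---|---|---|
| w1 | Th → Cx | 20 | 20 | 20 |
| w2 | Cx → Th | 5 | 12 | 5 |
| w3 | nRT → Th | 8 | 8 | 8 |
| w4 | DCN → Th | 25 | 9 | 20 |
| w5 | GPi → Th | 15 | 15 | 15 |
| w6 | Cx → nRT | 5 | 5 | 5 |
| w7 | STN → GPe | 19 | 5 | 5 |
| w8 | GPe → GPe | 5 | 5 | 5 |
| w9 | STN → GPi | 15 | 15 | 15 |
| w10 | Cx → STN | 20 | 20 | 20 |
| w11 | GPe → STN | 20 | 20 | 20 |

`healthy` oscillates in the gamma band (~43 Hz measured under the default
protocol), `tremor` in the tremor band (~4.1 Hz), `beta` in the beta band
(~19.7 Hz).  All seven populations except the decoupled DCN share one
frequency in each regime — a structural property of this mean-field
network, not an analysis choice.

## DBS forcing

Stimulation is a square wave of peak amplitude $A$ (a.u.) at frequency
$f$ (Hz), injected *inside the sigmoid argument* of one target population
(STN, Th, GPi or GPe — the four clinical targets):

$$\mathrm{DBS}(t) = A\,\frac{4}{\pi}
  \sum_{n=1,3,\dots}^{n_{max}} \frac{1}{n}\,\sin(2\pi n f t).$$

The series is evaluated literally (default truncation $n_{max} = 1001$),
so the Gibbs ripple of the truncated stimulus is an explicit, reproducible
feature rather than an accident of a solver; an exact square wave is
available behind `waveform = "ideal"` for sensitivity checks, and the two
agree to better than $10^{-2} A$ on the plateau interiors.  $A$ is the
*peak* value (the wave is $\pm A$), stimulation is on from $t = 0$ by
default with a configurable onset, and the frequency analysis discards
the first half of every run, so onset transients never enter the
statistics.  Inside the compiled right-hand side the series is evaluated
with the harmonic recurrence
$\sin((n{+}2)x) = 2\cos(2x)\sin(nx) - \sin((n{-}2)x)$; the R-level
`dbs_waveform()` sums the sines directly and the two implementations are
cross-checked in the tests.

## Numerical integration

All internal time is in seconds; time constants are converted from
milliseconds once, at parameter construction, so no ms/s mixing can reach
the $2\pi f t$ term of the forcing.  The state order
(Cx, Th, nRT, DCN, GPe, GPi, STN) is fixed across every vector, matrix
and file.

Two integrators drive the same compiled right-hand side:

* **adaptive stiff** (default for single simulations): `deSolve`'s
  `lsoda` with `rtol = 1e-6`, `atol = 1e-9` and the maximum internal step
  clamped to the 0.1 ms output step;
* **fixed-step RK4** at the 0.1 ms output step (the sweep/survey default,
  and the cross-check oracle).

The two agree to better than $10^{-3}$ (max-abs over 1 s) on all three
presets, and tightening the adaptive tolerances tenfold moves the final
state by less than $10^{-5}$ per component — both tested.  A pure-R
implementation of the derivatives (`network_derivatives()`) is exported
and integrates identically to the compiled code, which guards the C
implementation itself.

Initial conditions are not part of the model definition; the package
default starts every population at 0.1 (interior of the invariant box
$[0, k_e]/[0, k_i]$, whose forward-invariance is a tested property), with
an optional seeded uniform draw in $[0.05, 0.2]$.  Each preset's
limit-cycle frequency is identical to within 0.25 Hz across random
interior initial states (tested), so this choice does not condition the
reported frequencies.

## Spectral analysis and classification

The analysis protocol simulates 4 s and analyses the final 2 s.  A 1 s
run with the second half analysed — the minimal protocol — cannot place a
4 Hz rhythm on a fine frequency grid with segment-averaged Welch
estimates, so the default `power_spectrum()` uses a single full-window
Hann segment, mean-removed and zero-padded to at most 0.25 Hz grid
spacing (0.15 Hz achieved at 10 kHz sampling); multi-segment averaging
with configurable overlap remains available through
`spectral_settings()`.

`dominant_frequency()` reports the maximal spectral peak above
`min_freq` (0.5 Hz), with two guards:

* a peak must exceed 10× the median in-band power (and a tiny absolute
  floor), otherwise there is no dominant frequency;
* strongly non-sinusoidal relaxation cycles can carry marginally more
  power in a harmonic than at the cycle rate (the tremor regime's
  thalamic trace has a 2nd-harmonic/fundamental power ratio of ~1.03), so
  when a local peak at $f_{max}/n$ ($n = 2..6$) holds at least 25% of the
  maximal peak's power, the fundamental is reported.  A pure tone or a
  mildly distorted cycle is unaffected.

**Oscillatory** (`is_oscillatory()`) is a two-part test: some non-DCN
population must exceed a peak-to-trough amplitude of $10^{-3}$ over the
analysis window, *and* the largest-amplitude population's spectrum must
contain a genuine peak as above.  The two parts respectively reject fixed
points and slow aperiodic drift.

**State labels** (`classify_state()`): tremor [3, 8) Hz, beta [13, 30) Hz
and gamma [30, 90) Hz bands; `other_band` for oscillatory states between
bands (the ~12 Hz state reached from the tremor column by raising
$w_7$ to 22 is the prominent example); `non_oscillatory` otherwise.
Stimulated runs are classified against their own no-DBS baseline, with
precedence suppression → entrainment → band:

* **suppressed** (`is_suppressed()`): the largest peak-to-trough
  amplitude over the populations that are neither the DCN nor the
  stimulated target falls below `suppression_fraction` (default 0.2) of
  the same baseline measure, and any residual rhythm is not slower than
  the baseline's.  The stimulated population is excluded because it
  tracks the forcing directly whatever the network does — GPe
  stimulation, for instance, silences the GPe's slow rhythm while the
  rest of the network keeps oscillating, and that state must not read as
  network suppression.  Threshold results are always reported together
  with the fraction.
* **entrained**: dominant frequency within one grid bin of the
  stimulation frequency.

The 0.2 fraction is a formalization of "high-amplitude low-frequency
activity replaced by low-amplitude high-frequency activity".  It is
validated by the amplitude sweeps, where suppression onset is a sharp
bifurcation-like event and the resulting integer thresholds (beta/STN 4,
tremor/Th 5, tremor/GPi 1 a.u. at 120 Hz) are insensitive to the exact
fraction.  Along the *frequency* axis, by contrast, the network entrains
1:1 at every stimulation frequency and its amplitude decays smoothly
(fractions of baseline ≈ 0.45, 0.33, 0.25, 0.19 at 40-70 Hz for the
tremor state at 5 a.u.), so the "switch complete" frequency is directly
set by the fraction: 70 Hz at 0.2, 50 Hz at 1/3.  The package reports the
0.2-based value and treats the sensitivity as a property of the
definition, not of the network.

**Phase ordering** (`phase_order()`) ranks oscillating populations by the
circular-mean delay from each thalamic peak to their nearest peak, wrapped
to $[0, T)$; ties within one sample step are broken by cross-correlation
lag.  Delay-after-the-thalamus is the natural convention here because the
thalamus leads every oscillatory regime of this network; in the tremor
state the order is Th, Cx, nRT, STN, GPe, GPi.

**Burst structure** (`is_bursting()`): per-cycle peak-to-trough
amplitudes (cycles split at successive troughs) are tested for
multimodality with Sarle's bimodality coefficient (> 5/9), requiring a
minimum relative spread of 0.1 so steady rhythms can never qualify.
Under low-frequency stimulation the bursting concentrates in the
stimulated population (the STN fires repeating multi-cycle volleys within
each stimulus period), so the network-level default scans all non-DCN
populations.

## The experiment battery

* `random_survey()` draws all 11 weights from U[0, 30] and `ext` from
  U[0, 10] (one seeded generator, fixed draw order w1..w11 then ext, so
  record tables are bit-reproducible), simulates each vector, and streams
  one summary record per draw.  Surveys use 2 s of activity (1 s
  analysed) with the fixed-step integrator: enough to classify
  oscillation and place the dominant frequency on the 0.25 Hz target
  grid, at ~35 ms per simulation so a 10,000-draw survey completes in a
  few minutes.  Per-weight ranges (including zero-width pins) support
  conditioned surveys.
* `single_param_sweep()` / `pairwise_sweep()` vary one or two parameters
  over integer-stepped grids (0-40 by default in the CLI), everything
  else held at the base column; 4 s per simulation.
* `dbs_sweep()` runs the amplitude × frequency grid for one target
  (defaults A ∈ 0..10 a.u., f = 120 Hz; the frequency experiments use
  10-160 Hz in steps of 10), classifying every record against the no-DBS
  baseline.
* `find_threshold()` formalizes "from x a.u. and above": the smallest
  grid value from which the predicate holds through the end of the grid;
  non-monotone satisfaction warns and, if nothing holds through the end,
  yields no threshold.

Records carry the full parameter vector, so any row can be re-simulated
independently; sweep/simulate coherence is a tested property.

## What the simulations do and do not show

Everything here is a deterministic, noise-free mean-field model: it
emulates the *frequencies, relative amplitudes and phase relations* of
pathological network rhythms and their response to periodic forcing, and
the regime geometry of the weight space.  It contains no spatial
structure, conduction delays, stochastic spiking, plasticity, or
biophysical electrode/axon detail, and all populations share a single
rhythm whenever the network oscillates — so agreement of the test suite
with the documented regime properties validates the dynamics of this
idealized circuit, not any claim about individual neurons or about
patient recordings.  Clinical interpretation (target choice, parameter
programming) is out of scope.

## Known limitations

* The tremor-state slowing under weak STN stimulation measures 3.8 Hz
  here against a documented value of roughly 3 Hz; the direction and
  presence of the slowing are robust (to integrator, duration, waveform
  truncation), the magnitude is not reproduced.
* The "switch complete by 50 Hz" frequency boundary depends directly on
  the suppression fraction (see above); only with the laxer 1/3 fraction
  does the 0.2-convention grid search reproduce 50 Hz.
* Survey runs use the 2 s protocol; very slow rhythms (< 1 Hz) would be
  under-resolved there, though none arise in the surveyed ranges.
* `find_threshold()` is a grid search; no numerical continuation of limit
  cycles is attempted, so thresholds are only as fine as the grid.
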