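---
title: "Models and methods behind picramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind picramp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picramp)
```

picramp phenotypes spinal motoneurons from slow-ramp patch-clamp protocols:
persistent inward currents (PICs) from voltage bi-ramps, input conductance
and capacitance from voltage steps, frequency–current (F-I) gain from
current bi-ramps, inclusion filtering and hypoexcitability classification,
soma-volume morphometry, and the group-level statistics. Because raw
recordings of the motivating experiments are not publicly deposited, the
package ships a ground-truthed conductance-model generator of synthetic
recordings so that every analysis stage can be validated against known
cell parameters. This vignette documents the models, the calibration
choices, the numerical conventions, and what the synthetic validation does
and does not establish about real data.

## Units and the membrane model

All quantities use ms, mV, pA, nS and pF. In these units pA/nS = mV and
pA/pF = mV/ms, so the membrane equations carry no conversion coefficients.

A synthetic motoneuron (`cell_params()`) is a single compartment:

$$C \frac{dV}{dt} = -G_{leak}(V - E_{leak}) - I_{PIC}(V) + I_{inj} + \xi$$

with a non-inactivating Boltzmann PIC conductance

$$I_{PIC}(V) = G_{pic}\, m(V)\,(V - E_{pic}), \qquad
  m(V) = \frac{1}{1 + e^{(V_{1/2} - V)/k}}$$

and Gaussian current noise $\xi$ (SD `noise_sd`, 5 pA by default in the
group presets). Spikes are integrate-and-fire: on reaching $V_T$ the sample
is stylized to the recorded overshoot `ap_peak`, the membrane resets to
`V_reset` and holds for a lumped refractory/AHP period `t_ref` (25 ms, which
places mid-range firing in the 20–40 Hz band typical of neonatal
motoneurons). With no PIC the closed-form leaky-integrate-and-fire rate

$$f(I) = \left[t_{ref} + \tau_m
  \ln\frac{I/G + E_{leak} - V_{reset}}{I/G + E_{leak} - V_T}\right]^{-1}$$

is exact and serves as the independent oracle for the current-clamp
integrator and the F-I analysis.

Activation is instantaneous and single-compartment by design: dendritic PIC
compartments, Ca/Na PIC decomposition and channel kinetics are out of
scope. Integration is forward Euler (in C++), 0.01 ms for current clamp and
0.1 ms for voltage clamp; a convergence test checks that halving dt moves
the k-th spike by less than k steps and brings the mean period closer to
the closed form.

### Why $V_{1/2} = -31.2$ mV and $k = 4.3$ mV

The experimental tables report *emergent* PIC features, not channel
parameters: onset voltage about $-46$ mV and peak-current voltage about
$-21$ mV. For a Boltzmann conductance with reversal $E_{pic}$, the
peak-current voltage solves $(1 - m(V^*))(E_{pic} - V^*) = k$ and the onset
voltage is where the current crosses the onset criterion ($-10$ pA for a
$-200$ pA cell). With $E_{pic} = +30$ mV these two constraints pin
$V_{1/2} = -31.2$ mV, $k = 4.3$ mV (grid-verified: peak $-21.0$, onset
$-46.0$). Steeper or more negative midpoints shift the onset tens of mV
away from the reported values. The peak voltage is independent of PIC
amplitude; the onset voltage moves by $k\,\ln(A_1/A_2)$ between amplitude
presets, a 2–4 mV spread that sits inside the reported SDs.

Per-cell PIC strength is specified as a target amplitude (the most-inward
leak-subtracted current on the $-80\to+10$ mV ramp) and converted to
$G_{pic}$ by `calibrate_gpic()`; since $I_{PIC}$ is linear in $G_{pic}$ the
conversion is a single division by the unit-conductance grid minimum.

### Group presets

`motoneuron_presets()` encodes the study conditions: per-group normal
distributions of input conductance, resting potential, capacitance, spike
overshoot and threshold, and PIC amplitude, with the published means and
SDs for wild type (WT), the hG93A-SOD1 ALS model (mSOD1), and both groups
under the S6K1 inhibitor PF-4708671, plus the hypoexcitable subpopulation
observed among treated mSOD1 cells. Cohort draws are truncated-normal
(redrawn) at physiological validity limits: positive conductance and
capacitance, threshold between rest and spike peak, strictly inward PIC
target.

### The hypoexcitable mechanism

The experiments describe treated-mSOD1 cells that cannot sustain firing on
slow current ramps — even at doubled ramp amplitude — yet still fire a
single spike to a 1 nA step. No biophysical mechanism is reported, so the
generator implements a minimal one: a slow spike-availability resource.
Each spike multiplies availability by $1-u$; a spike requires availability
$\ge a_{min}$; availability recovers to 1 with time constant
$\tau_{avail}$. Hypoexcitable presets use $u = 0.65$, $a_{min} = 0.5$,
$\tau_{avail} = 30$ s: the first spike drops availability to 0.35, blocking
further spikes for roughly 8 s regardless of drive — one spike per
protocol, occasionally two on the long ramps — while normal presets have
$u = 0$ and remain exactly LIF+PIC. Because the phenotype is *defined* by
the ability to fire a single spike to the 1 nA step, hypoexcitable
parameter draws are additionally redrawn until the quasi-static rheobase
$\max_{V \le V_T}\,[G_{leak}(V - E_{leak}) + I_{PIC}(V)]$ is below 950 pA;
without this coherence constraint a sizeable fraction of draws could never
reach threshold at 1 nA and would be unexcitable rather than hypoexcitable.

## Voltage-clamp analysis

The ideal-clamp response is $G_{leak}(V-E_{leak}) + I_{PIC}(V) + I_{cap} +
\xi$, where $I_{cap}$ is the command derivative filtered through a single
exponential of time constant $C/G_{leak}$ — the whole-cell charging
transient. A voltage step therefore produces a decaying exponential whose
time constant, multiplied by the steady-state conductance from the same
trace, yields the capacitance estimate (`estimate_capacitance()`); the
published tables never state a capacitance method, so the exponential-fit
convention is a package choice. A ramp produces a constant $C\,dV/dt$
offset that the leak fit absorbs into its intercept.

Input conductance (`estimate_input_conductance()`) is the least-squares
slope of steady-state current (mean over the last 20% of each step) versus
step voltage across the small-step family around $-80$ mV, where the PIC is
deactivated ($m(-70) \approx 10^{-4}$). Whether the original analysis used
the step family or the ramp's subthreshold slope is unstated; steps are
used here, matching the protocol order in the methods.

Leak subtraction (`fit_leak()`, `extract_pic()`) fits a line to the
ascending-limb current over a subthreshold voltage window, default
$[-80, -60]$ mV — below every reported onset voltage — and subtracts it.
Two numerical guards matter:

* samples within 250 ms of the ramp start are excluded from both the fit
  and the PIC search (`settle_ms`, `exclude_start_ms`), because the
  capacitive ramp-onset transient ($\tau = C/G_{leak}$, up to ~50 ms for
  large, leaky cells) otherwise tilts the fitted line or masquerades as an
  inward deflection;
* the leak-subtracted current is smoothed with a 201-sample moving average
  (about 20 ms at 10 kHz) before the minimum is taken, so that with 5 pA
  noise the amplitude is not the extreme-value-biased minimum of ~10^5
  noisy samples. The smoothing bias at the PIC minimum is below 0.1 pA.

The PIC measure is the minimum of the smoothed leak-subtracted current on
the ascending limb (signed, inward-negative, as amplitudes are reported),
the command voltage there (peak voltage), and the onset voltage: the lowest
voltage from which the smoothed current stays below $-10$ pA until the
minimum, sustained for at least 50 ms. The onset criterion is a package
convention — the source analysis gives none — and onset is flagged
undefined when the criterion is never met (e.g. a null PIC). Descending-limb
hysteresis is deliberately not quantified.

One residual-error mode is worth knowing: the Boltzmann tail inside the
leak window (about $-0.6$ pA at $-60$ mV for a $-250$ pA cell) tilts the
fitted slope by ~0.01 nS, which the ~50 mV extrapolation to the PIC peak
converts into a 1–2 pA amplitude error. The end-to-end tolerance is
therefore max(1%, 2 pA), verified over 50 random noiseless cells; users
wanting sub-pA accuracy can end the window at $-68$ mV.

## Current-clamp analysis

Spikes are upward 0 mV crossings reduced to local maxima (matching the
"peak > 0 mV" inclusion criterion); the per-spike threshold is the voltage
where dV/dt first exceeds 10 mV/ms before the peak (common convention;
unstated in the source). The F-I relationship assigns each adjacent spike
pair a point: instantaneous frequency 1000/ISI against the injected current
at the *second* spike of the pair — the "corresponding current" wording
does not resolve the convention, and the second-spike choice makes the
point causal (the ISI ends there). Points are tagged ascending/descending
at the command peak, each phase is fitted by least squares, and slopes are
reported in Hz/nA. All ISIs are used (whether the original fits dropped the
first ISI is unstated). $I_{on}$, $I_{off}$ are the currents at first and
last spike; $\Delta I = I_{off} - I_{on}$ holds by construction. Rheobase
is the smallest step of a series that evokes a spike, and the
repetitive-firing assay counts spikes inside a prolonged (800 ms) 1 nA
step window.

## QC and classification

`apply_inclusion_filters()` transcribes the stated inclusion rules with
their exact inequality senses: soma diameter > 20 um, RMP < -50 mV, AP peak
> 0 mV, input resistance < 110 MOhm (derived as 1000/G_in), series
resistance < 25 MOhm, and exclusion when RMP or Rs drift *exceeds* 10
units. Missing metrics make a filter indeterminate and fail the cell.
`classify_hypoexcitable()` requires few spikes (<= 4; the reports show ~2
and give no number) on both the standard and the double-amplitude ramp,
*and* at least one spike to the 1 nA step; a cell silent under all three
protocols is flagged unexcitable, not hypoexcitable. Classified
hypoexcitable cells keep their records with F-I fields undefined rather
than being dropped.

In simulated studies the recording metadata (series resistance, drifts) are
drawn inside the inclusion limits: the generated cohort represents the
cells that survived QC, matching how the published group sizes are defined.

## Group statistics

Raw-data inference uses the standard machinery (`aov`, `TukeyHSD`,
`chisq.test`-equivalent Pearson statistic, `lm`). Because the published
tables print only mean ± SD with N, the package adds summary-statistic
variants: `anova_from_summary()` rebuilds the between/within sums of
squares from (mean, SD, N) and is algebraically identical to `aov` on any
data set with those summaries (tested to 1e-9 under exact reconstruction),
and `welch_t_from_summary()` re-tests printed pairwise comparisons. The
original post hoc tests were Tukey comparisons within four-group ANOVAs;
from two printed groups alone, Welch's t is the conservative recomputation,
and the published significance bounds (p < 0.05 / p < 0.01) are robust to
this substitution — a simulation check shows four-group Tukey at the
published presets flags the key PIC comparison at p < 0.01 in >= 95% of
replicates.

Soma-volume histograms use half-open lower-inclusive 5000 um^3 bins
(edge values go up), within-group percentages, and the upper-tail
percentage above 15000 um^3. The published chi-square for the binned
treated-vs-untreated comparison (56.259) cannot be recomputed — the
underlying bin counts are not published — so the chi-square routine is
verified on synthetic histograms (hand-computed 2x2 tables, a multinomial
Monte-Carlo oracle) instead.

## Soma-volume distributions and the mixture calibration

WT, WT+PF and mSOD1+PF soma volumes are single normals at their printed
mean ± SD. The untreated mSOD1 distribution is bimodal — a normal-sized
peak plus a large-cell peak — and only three constraints are printed:
overall mean 14156.13, overall SD 3920.44, and 38.1% above 15000 um^3.
With component 1 pinned to the WT normal (the natural reading of "one peak
matching wild-type"), exact mean and SD leave a one-parameter family in the
weight, and the tail over that family never goes below 38.85%: the three
printed values are mutually incompatible with that pinning by ~0.75
percentage points. The shipped mixture (`solve_bimodal_mixture()`) keeps
mean and SD exact and takes the closest tail: weights (0.475, 0.525),
means (11812.62, 16276.45), SDs (2653.22, 3666.34). Sampled tails land
near 38.8–39.0% at n = 10^5. Note the WT normal itself implies an 11.5%
tail where 21% is printed — the real distributions are right-skewed — so
tail percentages of the *single-normal* groups are not expected to match
print, and only the mSOD1 mixture's three calibrated summaries are
asserted.

## Morphometry

`render_label_volume()` voxelizes spheres of requested volumes (1 um
isotropic voxels by default; anisotropy must be declared explicitly) at
non-overlapping grid positions; it is the ground-truth fixture for the
measurement chain. `segment_somata()` thresholds and labels 6-connected
components on the voxel adjacency graph; `soma_volume()` is voxel count
times voxel volume; `max_diameter()` is the maximal pairwise distance
between surface-voxel centers (directional-extreme candidate reduction for
large regions), floored at one voxel diagonal so a single voxel reports its
diagonal. On rendered spheres with radius >= 10 voxels, volumes are
recovered within 3% and diameters within 1 um. The morphological selection
criteria of the original imaging ("thick apical dendritic arbor", pyramidal
shape) are not algorithmically reproducible and are out of scope; selection
is by size only.

## Interaction-score bridge

`combined_score()` integrates per-channel interaction probabilities by the
prior-corrected noisy-OR used by the major interaction databases (default
prior 0.041, exposed as a parameter), and `cross_set_edges()` extracts the
score-sorted edges bridging two gene sets (default cutoff 0.4,
medium confidence). Database snapshots are consumed as TSV inputs — no live
queries — and the packaged seven-pair pathway-bridge table is fixture data
from a specific database version, not a recomputed result.

## Reproducibility, problem sizes, and what the tests show

Every stochastic routine takes an explicit integer seed and is
bit-reproducible from it; a full simulated study (`run_study()`) derives
all per-cell and per-group seeds from one master seed, and rewriting its
report with the same seed is byte-identical. Default study sizes are the
published cohorts (25/22/21/24 cells with 4 hypoexcitable; 120/60/75/76
soma volumes); the validation suites use 50-cell noiseless recovery runs,
a 200-cell classification cohort, and 10^5-draw distribution checks, sizes
at which Monte-Carlo error is comfortably below the asserted tolerances.

The synthetic generator emulates the *statistical* structure the analysis
assumes — linear leak, one Boltzmann PIC, stylized spikes, white current
noise, normal parameter scatter, QC-conforming metadata. It does not
emulate series-resistance and space-clamp artifacts, dendritic PIC
hysteresis, channel kinetics, spike-frequency adaptation, electrode drift,
or skewed soma-size distributions. Passing tests therefore certify that
the pipeline recovers known ground truth under its own model assumptions
and reproduces the printed, recomputable statistics; they do not certify
accuracy on recordings whose physics violate those assumptions.
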