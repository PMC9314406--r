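---
title: "Modelling the development of binocular congruence in primary visual cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of binocular congruence in primary visual cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Neurons in primary visual cortex are orientation selective before the eyes
open, driven by waves of spontaneous activity that sweep over each retina
independently. A neuron's preferred orientation measured through the left
eye is therefore initially uncorrelated with its preference through the
right eye — yet in the adult the two monocular preferences agree to within
a few degrees. `binodev` simulates a mechanistic account of how this
congruence is acquired, in the cat's X-cell pathway: Hebbian plasticity in
the geniculocortical synapse first builds monocular orientation tuning
from drifting retinal waves, and then — once stimulation becomes
binocular — resolves the interference between on-centre input from one
eye and off-centre input from the other by re-weighting the two eyes'
inputs at each visual-field location. The same process, combined with the
unstable binocular fixation of the very young animal, produces a spread
of preferred binocular disparities; and where the two monocular
preferences start out near-orthogonal, it produces ocular dominance.

## Model structure

Each subcortical **channel** is a chain of one cone, one bipolar cell, one
ganglion cell and one geniculate relay cell sharing a visual-field
position. Off-centre channels sit on a square lattice (spacing 0.2 deg),
on-centre channels on a second lattice displaced by half a spacing so its
four innermost nodes straddle the field centre; both are jittered with
Gaussian deviates, independently per eye. The full-scale 10 x 10 deg
field holds 2601 off- plus 2500 on-centre channels per eye, 10,202 in
all. Cortical neurons sit on an unjittered grid (0.2 deg spacing), one
excitatory and one inhibitory cell per node.

Every stage integrates its input with first-order dynamics and, where
spiking, rectifies its generator potential into an impulse rate
(`rate = k_rect * max(p, 0)`). Signals converge with Gaussian attenuation
`exp(-d^2/r^2)`: a single subcortical function (radius `r_sub` = 0.4 deg,
folded into the closed-form stimulus drive) and a wider cortical function
(`r_cort` = 0.95 deg) for geniculate input to both cortical classes and
for the inhibitory-to-excitatory projection. Synaptic weights are the
product of a developmental modulation factor and this attenuation,
normalised so each neuron's weights sum to one — which pins every
neuron's resting potential to its presynaptic resting value. The
inhibitory cell has two compartments: a fast soma and a slow axon
(`tau_inh` = 100 ms) that delivers delayed inhibition. With the
inhibitory-to-excitatory modulation at its mature value the excitatory
cell rests at `k_gc * p_rest * (1 - k_ie)` = -8.778 mV, about 9 mV below
threshold — the "iceberg" that sharpens selectivity.

Stimuli are drifting sinusoidal gratings (default contrast 0.3, 0.5
cycles/deg, 2 Hz), whose subcortical drive has the closed form
`c * exp(-r_sub^2 * sf^2 / 4) * cos(sf*(u + offset) - tf*t)` along the
motion axis `u`, and flashed 1-deg squares for receptive-field mapping,
whose drive is a product of error-function differences. Both closed forms
are verified against brute-force quadrature of the defining
cross-correlation in the test suite.

## Numerical paths

Responses are computed two ways. The reference path integrates all
coupled equations with a classical Runge-Kutta scheme (`dt = tau/10`)
from the resting state. The fast path exploits the periodicity of grating
responses: each stage is applied per Fourier harmonic of the waveform
(one period sampled at `n_time` points), with every rectification applied
pointwise on the time grid. At `n_time = 256` the two paths agree to
better than 1e-3 in relative F1 amplitude on responsive neurons; the
development loop uses `n_time = 64`, which is ~100x faster per evaluation
and accurate to about 1% (the residual is quantisation of the
rectification zero-crossings, O(1/N^2)). Development only requires a
self-consistent response measure, so the coarser grid is used there;
interocular offsets are restricted to values that are integer shifts of
this grid, making offset stimuli exact column rotations.

The development inner loop is compiled (RcppArmadillo). Because one cycle
changes a single channel's modulation column, the loop maintains per-eye
input numerators as rank-1 updates and rebuilds them from scratch every
`refresh_every` cycles to cancel floating-point drift; checkpoint
boundaries align with these rebuilds so interrupted runs resume
bit-identically. A pure-R single-cycle reference implementation is kept
alongside and the two are required to agree exactly in the tests.

## The development procedure

Development proceeds in cycles. Each cycle selects one channel uniformly
from both eyes and provisionally adds 0.2 to the modulation of its
synapses onto every cortical excitatory neuron (clamped to [0, 2]). The
model is stimulated with gratings drifting in all 16 directions — in
phase 1 through the selected channel's eye only, the fellow eye at zero
contrast; in phase 2 through both eyes, at 5 interocular offsets evenly
spaced in [-0.5, 0.5] deg, the right eye's grating shifted along the
motion axis. Each neuron independently keeps the increment if its maximum
response over the ensemble grew, and otherwise reverts that synapse to
its previous value minus 0.2. Cycle counts give each channel about 5
selections in phase 1 (50,000 cycles at full scale) and 7.5 in phase 2
(75,000), enough for a consistently-judged synapse to traverse the full
[0, 2] range. During phase 1 the inhibitory-to-excitatory modulation
ramps linearly from 1 to `k_ie`, deepening the iceberg as selectivity
grows.

Three design points deserve comment, because the verbal description of
the procedure leaves them open and they decide whether the mechanism
works at all:

* **Comparison baseline.** The accept test compares the ensemble response
  with the same ensemble evaluated on the incoming state within the same
  cycle (`baseline = "increment"`). Cached-baseline variants ("the
  response on the previous cycle") are provided but are noise-dominated:
  a single channel's increment changes the response by the same order as
  the previous cycle's revert, and — in phase 1 — as the other eye's
  intervening updates, so cached comparisons misclassify roughly half of
  all cycles and the modulations random-walk instead of segregating.
* **Response measure.** The accept test uses the F1 amplitude of the
  excitatory *generator potential* (`measure = "potential"`). Under
  stimulation the untuned inhibitory population holds excitatory cells
  15-22 mV below threshold, and much of the population crosses threshold
  only transiently late in development; an impulse-rate measure therefore
  silences plasticity exactly where it is needed (a silent neuron's
  response cannot increase), while the depolarisation-based measure is
  graded everywhere — consistent with the voltage dependence of the
  synaptic plasticity it abstracts. Rate-based measures (`"f1"`,
  `"peak"`) are available for comparison.
* **Per-condition baselines.** In phase 1 each neuron keeps separate
  baselines per stimulated eye for the cached variants; comparing a
  left-eye response against a right-eye baseline lets whichever eye is
  momentarily stronger ratchet the other to extinction.

The mosaic jitter SD defaults to 0.1 deg (half the channel spacing). The
on/off density fluctuations that seed symmetry breaking scale with this
jitter; at a quarter-spacing jitter they are too weak for measurable
monocular maps to form within the 5-selection phase-1 budget, while
half-spacing jitter also brings the mosaic's regularity index closer to
that of real beta-cell arrays.

## Analyses

All analyses measure the F1 amplitude of impulse rate, as in the
physiology the model emulates, over the central analysis window (6 x 6
deg at full scale; edges are excluded because convergence footprints are
truncated there). Direction tuning is fitted with a sum of two von Mises
lobes sharing a concentration `k`; preferred orientation is the preferred
direction mod 180 deg and bandwidth is the half-width at half-height
implied by `k` (`acos(1 + ln(1/2)/k)`). Interocular congruence is
quantified with the Fisher-Lee circular correlation on doubled angles and
with the SD of the wrapped (-90, 90] interocular difference. Disparity
tuning is measured with optimally oriented gratings over one spatial
period of interocular offset and fitted with a rectified cosine with the
spatial frequency held at the stimulus value; ocular dominance uses the
grating optimised for the dominant eye (`ODI = r_R / (r_L + r_R)`,
monocularity `2|ODI - 0.5|`, contrast 0.25); receptive fields are mapped
with light-minus-dark sparse squares on the generator potential; map
periodicity is the mean radial distance of the nearest off-origin
autocorrelation maxima, converted to cortical distance at 0.625 mm/deg.

## Scale presets and what the reduced runs show

A full-scale run (125,000 cycles over 10,202 channels) takes hours on one
core. The package therefore ships presets that preserve the
selections-per-channel statistics at smaller fields: `"scaled"` (4.8 deg
field, 2,402 channels, 12,010 + 18,015 cycles, 2 x 2 deg window, 121
neurons; about ten minutes end to end) is used for all quantitative
summaries and by `scripts/acceptance.R`; `"desk"` and `"test"` are for
property checks and unit tests.

At the scaled preset the model reproduces the phenomenon it was built
for: monocular orientation maps are present and mutually uninformative at
the end of phase 1, and after binocular development the left- and
right-eye maps agree (circular correlation above 0.8; wrapped-difference
SD near 9 deg), the binocularly measured map matches the monocular ones,
fixation offsets during development produce a spread of preferred
disparities (SD near 0.5 deg) that collapses when the offsets are ablated,
and end-state monocularity correlates with the phase-1 orientation
mismatch.

Two quantities are known not to transfer to the reduced scale, and the
package reports them as measured rather than adjusting conditions:

* **Rate-level bandwidth.** With responses marginal against the
  stimulated inhibitory DC, only the crest of the tuning curve crosses
  threshold, so the measured HWHH (~6 deg) is far sharper than the ~20
  deg of the full-scale account; matching it would need drive coherence
  near 0.9 at phase-1 end, which the 5-selection budget does not reach in
  this reimplementation under any accept-rule variant tried.
* **Contrast sensitivity** scales with end-state mask concentration times
  the dominant eye's weight share, which the small window overshoots
  (mean monocularity ~0.8), giving ~100 mV per contrast-unit instead of
  ~70.

The phase-1 interocular circular correlation is also a fragile statistic
at the reduced window: 2 x 2 deg spans only one or two orientation
domains, so the map correlation is carried by a couple of smooth spatial
modes and can scatter far from zero for a single seed even though the
underlying mosaics are independent by construction.

Passing the scaled checks shows that the implemented cascade, plasticity
rule and analyses interact as described; it does not certify behaviour on
real visual input (the model sees only gratings and sparse squares), nor
the exact full-scale values.

## Known limitations

* Geniculocortical plasticity is applied to excitatory neurons;
  inhibitory cells keep unit modulations. The source account is ambiguous
  on this point; untuned inhibition is exactly the iceberg mechanism the
  model relies on, and it makes the inhibitory drive precomputable per
  stimulus, which the compiled loop exploits.
* The steady-state path assumes periodic stimuli; transients (sparse
  noise) always use the time-domain integrator.
* No excitatory-to-excitatory intracortical connections, no
  contralateral bias, no conductance-based dynamics — all outside the
  modelled scope.
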