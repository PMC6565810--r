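---
title: "Eigenmode models and envelope networks of infant sleep EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenmode models and envelope networks of infant sleep EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Newborn infants cycle between two vigilance states — active sleep (AS, the
precursor of REM sleep, with continuous low-amplitude EEG) and quiet sleep
(QS, discontinuous high-amplitude *tracé alternant*). The transition between
them reorganizes cortical functional networks at the whole-brain scale, and
the strength of that reorganization differs between infants born extremely
preterm (EP) and healthy full-term controls (HC), with prognostic value for
neurodevelopmental outcomes. `sleepmodes` implements the full analysis chain
for this problem: amplitude-envelope functional connectivity over a
58-parcel bilateral cortical parcellation, network-level permutation
statistics, and a generative neural-field model in which cortical activity
is a noisy superposition of geometric eigenmodes whose weights shift between
sleep states. Because the underlying clinical recordings are not publicly
distributable, the package ships a synthetic-cohort generator that emulates
the study design end-to-end; every downstream stage is exercised against it.

## Cortical geometry and eigenmodes

The cortical surface is a triangulated mesh. The package's stand-in geometry
(`make_bihemispheric_mesh()`) is two mirrored ellipsoidal lobes with
semi-axes (60, 45, 40) mm separated by a 6 mm gap — a smooth approximation
of the infant cortex at term-equivalent age, when folding is still shallow.
The medial pole of each lobe is opened and the two pentagonal rims stitched
by a thin 10-triangle band so the mesh is one connected component. That
choice is load-bearing: on a connected surface the first Laplace–Beltrami
eigenmode is the global constant and the second is the left–right
antisymmetric pattern, reproducing the mode ordering the analysis assumes.
Two disconnected lobes would instead duplicate the constant mode.

Eigenmodes solve the Helmholtz problem `lap m_j = -k_j^2 m_j` on the
surface. `assemble_laplace_beltrami()` discretizes the operator with linear
finite elements — the classical cotangent stiffness matrix and a
barycentrically lumped (diagonal) mass matrix. `solve_eigenmodes()` then
solves the generalized symmetric eigenproblem `K m = k^2 M m` as a dense
symmetric eigendecomposition of `M^{-1/2} K M^{-1/2}`; with the meshes used
here (hundreds to a few thousand vertices) the dense solve takes seconds, is
exact to machine precision, and needs no shift-invert machinery for the
singular `k^2 = 0` pair. Validation rests on two oracles: the unit sphere,
whose spectrum is `l(l+1)` with multiplicity `2l+1` (the subdivision-3
icosphere reproduces the `l = 1, 2` clusters within 2%), and the
bihemispheric surface, whose second mode must classify as antisymmetric
under the mirror map. The higher modes (3-5) of the smooth two-lobe geometry are nearly
degenerate, and their spectral order can swap between mesh resolutions;
`model_modes()` therefore selects the field model's modes by symmetry label
(constant, first antisymmetric, first two symmetric higher modes) rather
than by raw index. Eigenvectors are sign-ambiguous; the package fixes
each mode's largest-magnitude entry to be positive (ties to the lowest
vertex index) so repeated solves are bit-identical. Within a degenerate
eigenvalue cluster individual vectors are still arbitrary up to rotation, so
tests assert on eigenvalues and symmetry labels, never on individual vectors
inside a cluster.

### Mode amplitude convention

`parcel_mode_values()` projects modes onto parcels (area-weighted vertex
means) and, by default, rescales every mode to unit mass-weighted RMS
amplitude over the surface, which makes the constant mode identically 1.
Under this convention a mode weight `a_j` is the oscillation amplitude
relative to unit-SD noise — a dimensionless signal-to-noise ratio — and the
fitted-weight range `0 < a' < 0.5` is meaningful. Raw mass-orthonormal FEM
modes scale as `1/sqrt(surface area)` (~0.004 here), under which any weight
below 0.5 would be numerically invisible against unit noise; we verified
this directly (connectivity moments are flat in `a'` under the raw scaling).
The reference analyses do not state their normalization; unit-RMS is the
only convention under which their stated ranges are self-consistent, and it
is recorded here as this package's design choice.

### Noise discretization

The model's spatiotemporal white noise is integrated over each parcel along
with the signal. For white noise the parcel average has standard deviation
`sigma/sqrt(n sources in the parcel)`, which depends on the source density,
not on the physics. The reference pipeline clustered 8014 cortical dipoles
into 58 parcels (~125 sources each); `parcel_mode_values()` therefore
defaults to `n_sources = 8014` so per-parcel noise matches that density
(`sigma/sqrt(~138)`) regardless of the mesh in hand. Passing
`n_sources = NULL` reverts to the mesh's own vertices as the noise
discretization, which is what the vertex-level simulator
(`simulate_field()`) necessarily uses; the two agree exactly in the
deterministic part and differ in parcel noise only by this density factor.

## Signal processing

All filtering is zero-phase Butterworth: a high-pass/low-pass pair, each
applied forward and backward (`filtfilt`). Orders are the smallest that meet
20 dB attenuation at the stop-band edges in a single pass, with a 0.5 dB
pass-band droop constraint so the forward–backward pass keeps in-band tones
within a few percent of unit gain (a plain −3 dB-at-edge design loses ~18%
at the center of the narrow alpha band after two passes). The four canonical
bands are delta 0.4–1.5 Hz, theta 4–8 Hz, alpha 8–13 Hz and low beta
13–22 Hz. The spectral-fingerprint machinery uses two log-spaced banks:
21 carrier bands (`f_k = 0.5 * 1.2^(k-1)` Hz, topping out at 19.2 Hz) and
15 amplitude bands (`f_k = 0.015 * 1.2^(k-1)` Hz, topping out at 0.19 Hz),
each with pass edges at `0.85 f`/`1.15 f` and stop edges at `0.5 f`/`1.5 f`.

Numerical caveats, all verified by direct measurement:

* Transfer-function Butterworth coefficients become singular in double
  precision at very low normalized cutoffs. The designer reduces the order
  until the realized impulse response is bounded and decaying; the lowest
  carrier bands (≤ 0.7 Hz at 100 Hz sampling) therefore realize reduced
  pass-band gain. Amplitude bands (0.015–0.19 Hz) are never filtered at
  100 Hz: envelopes are first decimated to 2 Hz (anti-aliased), where the
  normalized frequencies are well conditioned and all amplitude bands sit
  below the 1 Hz Nyquist.
* Resampling in `preprocess()` (0.15–45 Hz band-pass, decimation to 100 Hz,
  common-average re-reference) is Fourier-based: exact and ripple-free for
  band-limited signals, which the preceding 45 Hz low-pass guarantees. The
  installed polyphase resampler was measured to leave a 2-sample group delay
  and ~7% amplitude ripple, so it is not used.
* Envelopes are the magnitude of the analytic signal (Fourier method). For
  the fit's inner loop the analytic signal is reconstructed from the
  pass-band bins only, demodulated at 1/4 rate — numerically the same
  envelope (correlation > 0.997 with the full-rate computation; the
  difference is the filter's stop-band leakage) at a fraction of the cost.

## The connectivity estimator

Functional connectivity is the orthogonalized amplitude-envelope
correlation: parcel signals are band-passed into a carrier band; for each
ordered pair the least-squares projection of one signal on the other is
removed within non-overlapping 2 s windows (suppressing zero-lag leakage,
which instantaneous volume conduction and source cross-talk produce);
envelopes of the regressor and of the residual are correlated (Pearson)
over the full record with the first and last 2 s excluded (filter
transients); and the two directed values are averaged, making the estimator
exactly symmetric. Windows in which the regressor vanishes leave the other
signal untouched, and zero-variance residuals contribute 0 with a warning —
so a pair of identical signals scores 0, not 1.

A property of this estimator that matters for interpretation: under
independent inputs it is not unbiased. The windowed regression selectively
suppresses the residual's envelope where the regressor's envelope is large,
producing a small negative null bias (measured −0.033, SD 0.018, for the
alpha band at 300 s). Mixing two independent sources through an
instantaneous 2×2 matrix yields |correlation| < 0.08 with orthogonalization
against > 0.5 without, which is the estimator's purpose; the cost is the
small negative offset, which contrast statistics and the moment-matching
fit absorb because model and data pass through the identical pipeline. An
instantaneous (phase-projection) orthogonalization would be unbiased but is
not the windowed-regression estimator specified for this analysis.

With 58 parcels the full network has (58 × 57)/2 = 1653 edges. The
edge-reliability mask (`derive_edge_mask()`) emulates rejection of edges
indistinguishable from reconstruction cross-talk: synthetic parcel sources
with independent slow modulators are mixed through a distance-decay leakage
operator; each pair is re-simulated with a shared modulator (a rank-2
update of the mixed matrix) and its recovered connectivity compared with
the pooled surrogate distribution of non-synchronized pairs; edges whose
mean recovered value fails to exceed the 99th surrogate percentile are
rejected, and the same mask applies to every subject. The percentile is
pooled across all surrogate pairs; a per-edge variant would need far more
iterations per pair for a stable 99th percentile and the pooled reading
matches the reference description. Matrices are finally normalized by the
global sum of absolute weights (scale-free, idempotent; signs are kept).

## Network statistics

Contrasts are run at the edge level (paired t for the sleep main effect
across all subjects; pooled-variance two-sample t for the group main effect
on state-averaged networks and for the group-by-sleep interaction on
per-subject AS − QS differences), then cluster-corrected with the
network-based statistic: edges with |t| above the search threshold (3 for
canonical bands, 2.5 for the fingerprint grids) are kept, connected
components of the induced parcel graph are found separately for the
positive and negative tails, and each observed component's edge count is
referred to the permutation null of the maximum component size of its own
tail (5000 permutations at full scale; state-label swaps within subjects
for paired contrasts, group reassignment preserving group sizes otherwise).
p-values carry the +1 correction so they are never exactly zero. Effect
sizes are Cohen's d = (component mean t)/sqrt(df). The permutation engine
is vectorized (one matrix product per permutation; per-permutation
component search by union–find, cross-checked against `igraph` in the unit
tests), which makes the FWER calibration experiment (200 null cohorts ×
1000 permutations) a minutes-scale computation.

## The neural-field model and the moment-matching fit

Modelled activity is `Y = sum_j a_j m_j cos(2 pi nu t) cos(2 pi omega t) +
sigma eta` with `omega = 10` Hz (alpha carrier), `nu = 0.1` Hz (slow
amplitude modulation; the product is a beat, i.e. tones at 9.9 and
10.1 Hz), i.i.d. Gaussian `eta`, and the left-right mode fixed at `a_2 = 0`
(the observed networks are left-right symmetric; the constraint is
releasable). `nu` and `omega` are ordinary frequencies in Hz — the stated
parameter values make any other reading dimensionally inconsistent.
Connectivity depends only on `a_j / sigma`, so the fit proceeds in two
steps: with `sigma = 1`, model connectivity moments are precomputed on a
grid of `(a'_1, a'_3, a'_4)` over [0, 0.5] and each subject minimizes
`J = (mu_data - mu_model)^2 + (sd_data - sd_model)^2`, where the moments
are taken over the masked, normalized edge weights, identically for model
and data; afterwards `sigma` is set so the model time series matches the
empirical pooled SD, and `a_j = sigma a'_j`. One shared noise realization
(fixed seed) is used at every grid node, making the cost surface
deterministic; model evaluations are memoized so coarse-to-fine refinement
across subjects reuses nodes. The default scheme is a coarse 0.05-step grid
with local refinement to 0.0125; an exhaustive 0.0025-granularity search
(the reference's 201³ grid) is reachable by passing finer `refine_steps`,
at proportional cost.

### What the fit can and cannot identify (measured)

`J` imposes two constraints on three weights. We measured the moment map's
Jacobian along all three axes in several regimes (30–120 s records, both
moment normalizations, mesh-density and source-density noise): the
normalized moments `(mu, s)` are nearly collinear — an effectively rank-one
map — and even unnormalized moments leave the `a_3`–`a_4` trade direction
flat. The preimage of a subject's data summary is therefore a curve (or
surface) through the weight cube, and the grid argmin lands anywhere along
it that the deterministic surface wiggles happen to favor. The consequence,
quantified by the package's recovery experiment (50 synthetic subjects at
`a' = (0.30, 0.10, 0.05)`): per-coordinate recovery within ±0.05 succeeds
in only ~10–30% of subjects, and the noise scale `sigma` inherits the error.
This is a structural property of the two-moment cost, not of grid density
or record length (rates are equally poor at 0.0125 granularity and 120 s
records), and the reference's exhaustive grid has the same two-constraint
structure. What *is* identifiable is the direction the moments load on:
group-level state contrasts. In the end-to-end experiment (94 synthetic
subjects, QS generated with more uniform-mode energy than AS), the fitted
`a'_1` group means are nearly unbiased (0.36 QS vs 0.21 AS against
generating means 0.33/0.21) and the sleep main effect is decisive
(F(1,92) ≈ 50, p ≈ 3×10⁻¹⁰) even though individual fits scatter with
SD ≈ 0.15. The subtler group-by-sleep interaction planted in the generator
(EP state difference 0.08 vs HC 0.15) does not survive that scatter at any
scale we tested; the acceptance suite reports this honestly rather than
enlarging the generated attenuation post hoc.

## The synthetic cohort

`cohort_spec()` defaults encode the emulated study: 42 EP and 52 HC
subjects, both states per subject, 300 s at 100 Hz, conceptional age
~41 weeks at recording. Mode-weight means per group and state put more
uniform-mode energy in QS than AS (0.35 vs 0.20 in HC, following the
reported direction and magnitudes), slightly less anteroposterior energy in
QS, and an attenuated state difference in EP (0.30 vs 0.22); between-subject
variation is normal truncated at zero (weights are amplitudes) with SD
0.05, and noise SD is 1. All randomness flows from one cohort seed through
per-subject derived seeds, so any subject is independently reproducible and
the cohort is bit-identical under its seed. Outcome scores
(`simulate_outcomes()`) are linear in a per-subject connectivity-change
covariate plus age and noise, with a negative default coupling for the
visual score and none for the social-emotional score, mirroring the
reported association structure. What the generator does *not* emulate:
realistic cortical folding, sensor-level EEG and its artifacts, true
vigilance-state dynamics (state is a label, not a process), or the
psychometrics of real developmental scales — so passing tests demonstrate
the pipeline's statistical behavior under the stated generative model, not
clinical validity.

## Problem sizes used by the tests and the acceptance script

The shipped experiments run at a demonstration scale chosen once: 60 s
records for fit-related experiments (120 s and 300 s were measured to give
the same qualitative conclusions), 120–150 summary edges for the moment
computations, a 0.05-step coarse grid with one 0.0125 refinement, 200 null
cohorts × 1000 permutations for the FWER calibration, and subdivision-3
geometry (1282 vertices) for fitting with subdivision-2 geometry for
combinatorial unit tests. The `"paper"` configuration preset restores the
full-scale settings (300 s records, 500 mask iterations, 5000 permutations,
0.0025 grid granularity).

## Known limitations

* The windowed-regression estimator's negative null bias (above) shifts all
  absolute connectivity levels; only quantities computed identically on
  both sides of a comparison should be interpreted.
* Per-subject mode weights from the two-moment fit are set-valued in
  practice; treat them as group-level quantities.
* The toy leakage operator is a Gaussian distance kernel, not a forward/
  inverse model; the reliability mask it induces is structurally, not
  anatomically, faithful.
* Lowest-band (≤ 0.7 Hz) carrier filters trade pass-band gain for numerical
  stability in transfer-function form.
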