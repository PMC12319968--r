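---
title: "Laminar inference for on-scalp magnetometer arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar inference for on-scalp magnetometer arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(opmlaminar)
```

## The problem

Cortical activity measured by magnetoencephalography (MEG) originates from a
folded sheet a few millimetres thick. Whether a measured signal comes from
the deep (white-matter boundary) or superficial (pial) side of that sheet —
*laminar inference* — is at the edge of what non-invasive recordings can
resolve. On-scalp optically pumped magnetometers (OPMs) sit much closer to
the brain than cryogenic sensors and may make this discrimination practical.

`opmlaminar` implements a complete simulation pipeline for studying this
question: it generates layered cortical geometry and configurable OPM-like
sensor arrays, simulates patch sources at controlled signal-to-noise ratios
(SNR), and attempts to recover the laminar origin from the sensor data alone
using two decision procedures built on empirical Bayes source inversion.

## Geometry: a synthetic two-surface cortex

Real laminar-inference studies use FreeSurfer white/pial surface pairs with
one-to-one vertex correspondence. This package removes the MRI dependency by
emulating the essential structure with nested perturbed icospheres:

* white, mid and pial surfaces share one triangulation (identity vertex
  correspondence), with default radii 70/71/72 mm — a 2 mm layer separation
  in the range of human cortical thickness — inside an 85 mm scalp sphere;
* a smooth seeded radial "bump" field (sum of 400 narrow exponential lobes,
  scaled to a 6 mm maximal amplitude) is added identically to every layer.
  The per-vertex separation therefore stays exactly 2 mm while the surfaces
  become non-spherical.

The bump is not cosmetic. Dipole orientations are the outward vertex
normals, and in a spherically symmetric conductor a radial dipole is
externally silent; on exact spheres every source would be invisible. The
bump tilts normals away from radial (median ≈ 8°, upper quartile ≈ 12° at
the default amplitude), giving each source a measurable tangential
component while keeping the layered structure intact. This understates the
orientation variability of real cortex (where normals are often nearly
tangential), so absolute signal amplitudes are conservative; laminar
contrasts, which depend on *relative* lead fields of corresponding
deep/superficial vertices, are preserved. By the hairy-ball theorem some
vertices remain nearly radially oriented and thus nearly silent — as an
unlucky subset of sources would be in any spherical-conductor study.

Default mesh resolution is icosphere subdivision 4 (2562 vertices per
surface, ≈ 4.7 mm spacing). With 5 mm FWHM patches this yields compact
patches of one to a few vertices; the anatomical meshes this emulates are
denser (≈ 1.7 mm spacing), so simulated patches here are closer to point
sources than in the full-scale setting.

## Sensor arrays

Sensors are packed on the scalp mesh by farthest-point greedy selection
until no vertex at the requested minimal pairwise distance remains — a
deterministic maximal packing given the seeded starting vertex. Each sensor
measures along one to three orthonormal axes: the radial axis `[x, y, z]`
(the scalp normal), a first tangential axis along the normalised
`[y, -x, 0]`, and their cross product. Where the tangential formula
degenerates (radial parallel to z) the first tangential axis falls back to
the tangent-plane projection of `[1, 0, 0]`; the formula's `[y, -x, 0]` is
normalised to unit length so all channels have uniform gain. Scalp–sensor
offset is applied by sliding sensors along their radial axes from their
scalp anchor points (6.5 mm emulates on-scalp OPMs; 20–40 mm emulates
cryogenic arrays).

Co-registration error is modelled as a *rigid* array misalignment: the three
canonical fiducials (nasion-like and two pre-auricular-like points on the
scalp sphere) are displaced by iid Gaussian noise per coordinate, a
least-squares (Kabsch) rigid transform from true to displaced fiducials is
estimated, and that transform is applied to all sensor positions and axes.
Data are simulated with the true array and inverted with the misaligned one.

The alternative generative model (AGM) deliberately mismatches simulation
and reconstruction: sensor positions receive 1 mm Gaussian jitter, and the
source meshes used for *simulation* are rigidly rotated by half the mean
inter-vertex angular spacing, so simulated dipole locations fall between
reconstruction vertices. (The anatomical analogue — re-sampling a denser
mesh at 11% instead of 10% of its vertices — would require re-triangulating
a point cloud; the rotation achieves the same "no shared dipole locations"
property on icospheres while keeping valid normals and geodesics.)

## Forward model

Fields are computed with the closed-form solution for a current dipole in a
homogeneous spherically symmetric conductor, evaluated at point
magnetometers and projected on each channel axis (units: fT per nAm,
positions in mm). On spherical geometry this coincides with the standard
single-shell approach used by MEG software, is exact, and is analytically
testable (radial dipoles silent, superposition, rotation gauge invariance —
all in the test suite). Realistic-boundary conductors (BEM/FEM) are out of
scope and noted in the run manifest as a substitution.

## Source simulation

A source is a Gaussian patch on one surface: weights
`exp(-d²/2σ²)` of geodesic distance `d` from the centre vertex,
`σ = FWHM/2.355`, truncated at one FWHM and normalised to sum to one.
Geodesics are Dijkstra shortest paths over the mesh edge graph with
Euclidean weights — an upper bound on the true surface geodesic whose error
is small relative to the patch scale on these near-uniform meshes (exact
geodesic backends could be substituted).

The patch drives a 20 Hz sinusoid (default 10 nAm peak moment — the
absolute moment is immaterial in per-trial-SNR mode) active during
[100, 500] ms of a 1 s trial sampled at 200 Hz, 200 trials by default. The
active window is placed to coincide with the ROI analysis window; its
400 ms span holds exactly eight cycles.

White sensor noise is added either at a target single-trial amplitude SNR
(`20·log10(A_signal/A_noise)` with `A_signal` the mean over channels of the
per-channel standard deviation of the noiseless trial), or at a fixed
magnitude `A_ref·10^(dB/20)` independent of the signal. The fixed mode
exists for offset sweeps, where signal-referenced noise would mask the
benefit of closer sensors; `A_ref` defaults to 0.01 fT so the mid dB levels
straddle the informative SNR range on the default geometry — only the
ordering across levels is meaningful. Averaging N trials of iid noise
improves SNR by `10·log10(N)` ≈ 23.01 dB at N = 200 (signal grows ∝ N,
noise ∝ √N).

Interfering brain noise adds Gaussian patches at random mid-surface
vertices whose dipole time courses are exactly band-limited Gaussian noise
(10–30 Hz, synthesised spectrally), scaled to 0.4 of the RMS moment of the
source of interest. Waveforms are drawn independently per trial by default;
a `coherent` flag repeats them across trials instead, for the reading in
which such noise survives trial averaging. Both behaviours are exposed
because "Gaussian random data" and across-trial coherence pull in different
directions; fixed source locations and amplitudes across trials are common
to both.

## Inversion and the free energy

Sensor data are reduced before inversion: optional full-trial Hann taper,
zero-phase 10–30 Hz band-pass (an order-4 Butterworth magnitude response
applied in the frequency domain), projection onto the orthonormal spatial
modes of the lead field (up to 274; with fewer channels, all of them), and
onto up to 4 temporal modes from the SVD of the trial-averaged data. The
reduced covariance is rescaled to unit mean eigenvalue; the scale depends
only on the data, so free energies of different source models on the same
dataset remain comparable.

The model covariance in mode space is a positive mixture
`C = h₀I + Σ hₖ L Qₖ Lᵀ` with log hyperparameters optimised by ReML (Fisher
scoring with monotone backtracking, mildly informative log-normal
hyperpriors N(−4, 16) on each log hyperparameter, components scaled to
trace m). The reported free energy is the Laplace approximation to the log
model evidence: the maximised objective plus `½ log|Σ_λ Π|`. With fixed
hyperparameters and no hyperprior it reduces exactly to the Gaussian log
likelihood, which is how the implementation is pinned against a brute-force
oracle in the tests.

Four functional priors are available:

* **EBB** — a single diagonal component with beamformer weights
  `wᵢ = ‖lᵢ‖²/(lᵢᵀC_y⁻¹lᵢ)` from the regularised data covariance
  (`C_y = S + 10⁻⁴·tr(S)/m·I`). The lead-field normalisation follows the
  classic implementation and is essential on this geometry, where
  near-silent sources would otherwise dominate; the unnormalised
  `1/(lᵢᵀC_y⁻¹lᵢ)` variant is available via `normalise = "none"`.
* **MSP** — a library of rank-one patch components `qqᵀ` (5 mm FWHM by
  default) at uniformly sampled centres per surface (default 128; the
  reference studies use 64 for runtime), optionally including designated
  vertices — the true source locations in matched ("idealised") runs, and
  never in AGM runs. A greedy search adds one component at a time, keeping
  the candidate that maximises free energy (ties to the lowest library
  index), stopping when the gain drops below 0.01 nats or 8 components.
* **IID** — identity source covariance (minimum-norm-like).
* **COH** — a Gaussian kernel of Euclidean inter-source distance (10 mm
  length scale), LORETA-like smoothness.

IID and COH exist to replicate the known negative result: priors without
sparse laminar structure cannot separate the surfaces (both sit at chance in
the reference study, with IID classifying everything superficial and COH
everything deep — two faces of the same depth-bias coin).

## The two laminar decisions

**Whole-brain**: invert once onto the pial-only and once onto the
white-only model (Hann + band-pass) and report `ΔF = F_pial − F_white`.
Positive favours the superficial surface; `|ΔF| > 3` (evidence ratio
e³ ≈ 20) marks a significant single-simulation decision.

**ROI**: invert once onto the combined two-surface model (no Hann). For
every vertex and trial, band power (variance of the band-passed posterior
time course, computed through the posterior projector without materialising
per-vertex time series) is contrasted between the active [100, 500] ms and
baseline [−500, 100] ms windows. Vertices with a paired t at or above the
75th percentile within their surface — signed t, linear interpolation;
simulated sources only add power, so the signed upper tail is the
informative one — enter the ROI together with their correspondence partners,
making the ROI closed under the pial/white pairing and at least 25% of each
surface. Per-trial ROI values (mean |power change| within the ROI per
surface) are compared by a paired t with a variance floor
`s₀² = 10⁻⁶ × mean squared ROI value` (the cited low-variance
regularisation is not reproduced in print; this floor is a documented
stand-in, and the plain paired t is the `variance_floor_rel = 0` limit).
Positive t favours pial; significance at the two-tailed critical t with
`n_trials − 1` df (1.9720 at 200 trials).

Both metrics are antisymmetric under exchanging the surface labels.

## Sweeps, seeds and statistics

`run_sweep()` crosses condition levels (SNR or noise magnitude, packing
distance, measurement axes, offset, fiducial error, simulated/reconstructed
patch FWHM pairs, brain noise, GM/AGM) and repeats each cell over randomly
sampled source vertices on each surface (60 per surface at full scale).
Every random draw derives from the master seed by stable hashing of the
condition tuple, so results are bit-reproducible, adding a condition level
leaves other cells unchanged, and per-cell caching makes interrupted sweeps
resumable. Fiducial errors are redrawn per simulated source, with the lead
fields rebuilt for the misaligned array each time.

Summaries report percent correct / percent pial / percent significant with
binomial standard errors. Exact two-sided binomial tests (chance 50%),
exact McNemar tests on discordant pairs, and logistic regressions of
outcome on the standardised ordered level index (IRLS, separation flagged)
are provided; for the logistic slopes only signs/directions are
interpretable, as the level coding is a convention.

## Reference studies and problem sizes

The packaged studies (`study_snr_recovery()`, `study_prior_mismatch()`) are
deliberately scaled down so a full run takes minutes on one CPU: subdivision
4 geometry, a 55 mm single-axis array (~16 sensors on this scalp), 20
sources per surface, 50 trials per source, and a 64-patch-per-surface MSP
library. At 50 trials the trial-averaging gain is ~17 dB instead of ~23 dB,
so the SNR axis is effectively shifted ~6 dB against the full-scale setting.
The qualitative structure survives the scaling: MSP + ROI accuracy rises
from chance at −40 dB to ceiling at −5 dB with no pial/white bias, and the
IID/COH controls stay at chance throughout. Headline percentages of
full-scale anatomical studies are anatomy-specific and not reproduction
targets.

## Known limitations

* Spherical-conductor forward model; no realistic inner skull, no BEM/FEM.
* Synthetic geometry: correct laminar topology, but no sulci/gyri, no
  orientation distribution matching real cortex, coarser meshes than
  FreeSurfer-derived surfaces.
* Point magnetometers: no pickup geometry, crosstalk, gain or cross-axis
  projection errors; no environmental interference, drift or movement.
* MSP uses greedy free-energy search, not full ARD with pruning.
* Passing tests demonstrate internal consistency and qualitative agreement
  with the laminar-inference literature on synthetic data — not performance
  on any real head.
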