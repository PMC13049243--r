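---
title: "Rosette cMRF: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rosette cMRF: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science implemented by `rosettecmrf`: the signal
model, each stage of the reconstruction pipeline, the synthetic data used for
validation, and the design decisions taken where the method leaves genuine
freedom. It states no empirical result beyond what the package's test suite
and acceptance script compute.

## The acquisition

Cardiac MR fingerprinting (cMRF) acquires a transient-state signal evolution:
over 15 heartbeats, each heartbeat contributes 12 FISP excitations
(TR 20.4 ms, a 245 ms diastolic window), with magnetization preparation
before heartbeats following a repeating five-beat block — inversion, none,
T2-preparation TE 30 ms, T2-preparation TE 80 ms, none. Flip angles follow a
raised-cosine ramp between 5.7 and 20 degrees, peaking at the 7th excitation
of each heartbeat so that both printed extrema are attained exactly (the
exact in-window shape is a package choice; only the range and "sinusoidal"
shape are prescribed).

Each excitation is read out with a rosette trajectory
\(k(t) = k_{max}\sin(2\pi\omega_1 t/T)e^{i2\pi\omega_2 t/T}\) with
\(\omega_1 = 11.5\), \(\omega_2 = 7.5\), \(T = 18.4\) ms, sampled at a
2.5 microsecond dwell. The readout crosses the k-space origin 24 times; the
22 interior crossings are complete edge-to-edge sweeps and become the echo
train (TE1 1.74 ms, spacing close to 0.8 ms). Echo splitting at the envelope
apexes reports the geometric spacing \(T/(2\omega_1) \approx 0.80\) ms; the
protocol's printed spacing of 0.79 ms is carried in the configuration.
Consecutive lobes are rotated by \(180^\circ\omega_2/\omega_1 = 117.39^\circ\).
Between excitations the whole rosette is additionally rotated by the golden
angle (111.246 degrees) so that, combined over the 180 excitations, every
echo owns a densely covered k-space disk. This per-excitation rotation is
essential: without it each echo would sample a single lobe forever and
neither field mapping nor per-echo imaging would be possible.

Because time within the readout and k-space radius are locked together in a
rosette, off-resonant spins blur and attenuate rather than shift. The
`response_function()` quantifies this: the density-weighted average of the
off-resonance phase factor over the readout, including the transverse decay
of the responding species. For a fat-like species (T2* 20 ms, the fat decay
constant used throughout the package) the 220 Hz response is about 3–4% —
the rosette's intrinsic fat suppression. Without decay the pure frequency
response is about 1.2%; the decay weighting concentrates the average on the
early readout and is the physically relevant number for real fat signal.

## Signal model and dictionary

Fingerprints are simulated with an extended-phase-graph (EPG) engine for the
spoiled FISP sequence: per TR an RF rotation, relaxation, and a unit
dephasing shift; inversions scale longitudinal magnetization by the
inversion efficiency (default 0.95, configurable — the protocol corrects for
it but prints no value); T2-preparation is ideal and instantaneous
(longitudinal scaling by \(e^{-TE_{prep}/T_2}\)). Thirteen dephasing orders
are retained (truncation error below 1e-8 at this flip-angle range). The
engine is vectorized across dictionary entries; a 500-isochromat Bloch
simulation with ideal spoiling serves as the independent oracle in the test
suite (equally spaced isochromats realize the EPG exactly, so the agreement
check is sharp).

Slice-profile correction discretizes the small-tip profile of the
Hamming-windowed sinc pulse (time-bandwidth 2.0) into 5 subslices spanning
the nominal slice; fingerprints are averaged across the resulting effective
flip scales. The dictionary covers T1 = (10:10:2000, 2020:20:3000) ms and
T2 = (6:2:100, 105:5:300, 310:10:500, 540:40:1200) ms — the last segment
enumerated as 540, 580, …, 1180 — keeping the 28 010 combinations with
T2 ≤ T1 (both the segment reading and the non-strict inequality are the only
choices consistent with that count). Signals are stored unit-normalized with
norms kept separately so matched amplitudes remain proportional to spin
density. The rank-10 temporal subspace is the dominant left singular space
of the fingerprint matrix.

The fingerprint models the contrast at TE1 only; T2* decay and the fat
chemical shift (220 Hz at 1.5 T, single spectral peak) act along the echo
dimension and are applied by the phantom simulator and estimated by the
mapping stages. This separation mirrors the five-stage pipeline itself.

## Encoding operator and reconstructions

The unknowns are complex subspace-echo images \(x_{s,e}\) (10 subspace
coefficients × 22 echoes). The forward model applies, per echo, coil
sensitivities and the static off-resonance phase \(e^{i2\pi b_0 TE_e}\)
(one phase per echo at its nominal TE; intra-echo blurring is accepted and
documented below), evaluates a Kaiser–Bessel gridding Fourier transform
(oversampling 2, kernel width 4, kernel taps wrapped modulo the periodic
k-grid) at that excitation's rotated samples, and weights excitations by the
subspace basis row. Forward and adjoint are exact transposes by
construction; the test suite checks the dot-product identity to 1e-6.

**Direct reconstruction** grids each echo's subspace-projected data with
Pipe–Menon density weights and combines coils conjugately. Two
normalizations are applied: the iterative density estimate is only
approximate, so images are divided by the reconstruction of a uniform unit
image (flat-field normalization), and by the squared coil RSS.

**Iterative reconstruction** minimizes a least-squares data term plus
locally-low-rank (nuclear norm on 8×8 patches across the subspace-echo
dimension) and anisotropic total-variation penalties by monotone proximal
gradient steps with backtracking; with both weights zero it reduces to plain
conjugate gradient.

**Deep image prior** optimizes an untrained convolutional encoder-decoder so
its output images are consistent with the acquired k-space. The generator
maps a fixed 32-channel noise field through five encoding stages (paired 3×3
convolutions, instance normalization, leaky rectification, 7% dropout, 2×
average pooling) and five decoding stages (2× nearest upsampling, skip
concatenation, an attention gate — rectification, learned channel-wise
scaling, sigmoid, applied multiplicatively — a single 3×3 convolution,
instance normalization and channel-wise scaling), then projects to
2 × 10 × 22 real channels read as complex subspace-echo images (channel
order: real/imaginary pairs, subspace-major, echo-minor). All forward and
backward passes are hand-written on channels × pixels matrices; the test
suite verifies the gradients by finite differences. Instance normalization
is load-bearing: without it the multiplicative depth of the generator makes
the optimization oscillate at any usable step size.

Three choices make the fixed 100-iteration budget effective, and are the
package's own engineering within the method's stated freedom:

* **Density-weighted loss.** The data-consistency residual is weighted by
  the density compensation function (an explicitly configurable option of
  the loss). This preconditions the normal operator toward a multiple of
  the identity, so gradient steps move directly in image space instead of
  spending iterations inverting the sampling density. Unweighted least
  squares remains available (`dcf_weight = FALSE`).
* **Warm start.** Before the data-consistency iterations the generator is
  regressed in the image domain onto the density-compensated adjoint images
  (150 steps; no operator evaluations, so cheap). The subsequent 100
  data-consistency iterations then refine from the gridding solution rather
  than from noise. A cold start (`warmup_iterations = 0`) reproduces the
  classic from-noise behavior and is used by the off-resonance-convergence
  test.
* **Output averaging.** The returned images average the outputs of the last
  10 iterations with the final dropout-free pass, an ensemble over the
  dropout/optimizer path that suppresses iteration-to-iteration fluctuation.

Adam is used with gradient clipping (global norm 10) and a step size of
3e-3 at the reduced scale; the data are rescaled so the preconditioned
least-squares solution has unit-order amplitude. The final projection layer
starts at zero so optimization begins from the zero image. Dropout is active
during optimization and disabled for the final inference pass. All
randomness (noise input, initialization, dropout) derives from the
configured seed, making the reconstruction bit-reproducible.

Including the off-resonance phase in the forward model accelerates
convergence on field-inhomogeneous data; the test suite restates this as an
operator-level property (the corrected model reaches a reference error level
at a lower iteration number than the uncorrected one on a fixture with a
±50 Hz field gradient).

## Field estimation

The per-echo images of the first subspace coefficient (fully sampled after
combining the rotated excitations) drive the pre-computation. The
off-resonance map is found by discrete search: per voxel, the water/fat
variable-projection residual is evaluated on a grid of candidate fields
spanning ±1/(2ΔTE); a small field-magnitude prior breaks the exact
water-only/fat-shifted degeneracy toward the solution nearest zero; iterated
conditional modes on the pixel neighbourhood graph then select the smooth,
period-unwrapped solution, followed by local quadratic refinement. At the
package's image sizes this exhaustive-search-plus-Markov-smoothing solver is
used directly (it is the natural desk-scale realization of graph-style field
mapping). Coil maps are Walsh-style: the principal eigenvector of the
spatially smoothed coil covariance over off-resonance-corrected echo images,
RSS-normalized and phase-referenced to the first coil.

## Parameter mapping

Stage 3 fits, per voxel, the dual-exponential chemical-shift model
\(S(TE) = W e^{-TE/T_{2w}^*} + F e^{-TE/T_{2f}^*} e^{i2\pi f_{fat} TE}\)
to the B0-demodulated first-subspace echo images by variable projection:
complex amplitudes are solved in closed form on a log-spaced grid over the
two decay constants, refined by shrinking per-voxel neighbourhoods; decay
estimates are clamped to [2.2, 200] ms. Stage 4 applies IDEAL with the
externally estimated field map (mirroring the pipeline's pre-computation
ordering): per voxel and subspace coefficient, the same two-component model,
with per-voxel decay constants from stage 3, is inverted across echoes,
yielding water and fat subspace images referenced to echo time zero. Both
components are then matched against the same compressed dictionary by
normalized complex dot product (ties broken toward the lowest entry index;
a separate fat dictionary is not available, a documented limitation). The
returned spin density is the projection onto the unnormalized atom, so water
and fat densities share a common scale, and stage 5 computes the
proton-density fat fraction with the magnitude-discrimination estimator
(|F|/|W+F| where fat dominates, 1 − |W|/|W+F| otherwise), which avoids the
noise floor bias of naive ratios at low fat fractions.

## Synthetic data

The phantom simulator is first-class, tested code. Voxel signals are the sum
of a water and a fat component, each evolving with its own EPG fingerprint
across excitations (the phantom tables carry separate fat relaxation values,
fixed at T1 250 / T2 60 / T2* 20 ms), each decaying with its own T2*
continuously along the readout time axis — not just at echo centers — so
echo splitting is honestly stressed, with the fat component precessing at
the chemical shift. Spatial encoding uses a wider gridding kernel (width 5)
than the reconstruction. Off-resonance enters exactly when constant within a
tissue label and by 6-knot linear time-segmentation for general smooth maps.
Complex Gaussian noise is seeded and scaled to a fraction of the peak signal
magnitude; the realized level is verified in the tests.

Two phantoms are provided. The geometric short-axis cardiac phantom (left-
and right-ventricular blood pools, myocardial ring, liver, subcutaneous fat
layer, muscle body) carries healthy myocardium T1 950 / T2 48 / T2* 30 ms /
PDFF 1%, with pathological variants replacing one property at a time
(1250 ms, 65 ms, 15 ms, 10%). Other tissues use representative values placed
on the dictionary grid. The 36-vial phantom is the full factorial of
T1 (300, 800, 1200) × T2 (30, 70, 150) × T2* (15, 30) × PDFF (5%, 15%).

What passing tests on these phantoms do not show: anatomical realism,
motion, flow, B1 inhomogeneity, multi-peak fat spectra, and concomitant
fields are all outside the simulation; results transfer to real data only to
the extent that those effects are secondary.

## Reduced desk scale

All shipped computations run on one CPU. The reduced profile ties the
k-space extent to the matrix (kmax = matrix/(2 FOV)), so matrix 64 with the
300 mm FOV uses kmax 106.7 1/m with identical readout timing, echo
structure and schedule; the full printed protocol corresponds to matrix 192
and kmax 320. Reconstruction uses every 2nd ADC sample (the union over 180
rotations remains several-fold oversampled per echo), a single simulated
coil and 48 network channels for the cardiac accuracy runs, and the
acceptance script runs the four cardiac cases (healthy and the three
relaxation pathologies) noiseless at matrix 64 with 100 DIP iterations. The
confounder analysis runs the 36-vial phantom at matrix 96 with the full
readout, 2.5% noise, four coils and a smooth off-resonance field, using the
direct reconstruction; regional fat fractions are taken from coherently
averaged spin densities (`roi_pdff()`), which cancels spurious fat of random
phase. Problem sizes are stated here as the package's validation choices.

## Numerical choices and known limitations

* The encoding model freezes relaxation and chemical shift at each echo's
  nominal TE. Within a 0.8 ms echo the water approximation error is ~1%,
  but fat rotates by ±32°, so data-consistency solutions inherit a small
  model mismatch wherever fat is bright. The mapping stages operate
  voxelwise on echo images and are insensitive to it; exact least-squares
  inversion of the frozen model (the unregularized iterative path) is the
  most exposed.
* Pattern matching quantizes T1/T2 to the dictionary grid (10 ms / 2 ms
  near the myocardial values).
* The dual-T2* variable-projection grid bottoms at the 2.2 ms clamp; decay
  constants at that boundary indicate an unreliable voxel, not a
  measurement.
* The B0 search assumes the single-peak fat model; multi-peak spectra would
  bias both the field map and the separation.
* Tissue regions are reported as mean ± voxelwise SD over the label mask
  eroded by one pixel — the package's ROI convention, which excludes
  partial-volume boundary voxels, chosen once for all analyses.
* The trajectory feasibility checker reports peak gradient and per-axis
  slew from finite differences; the printed slew limit's unit is stored as
  configuration without interpretation (typical hardware limits are in
  T/m/s).
* In the packed vial array the point-spread function of the reduced matrix
  couples neighbouring vials along the echo dimension; the resulting
  spurious-fat floor (15-25 percentage points under 2.5% noise) swamps the
  5-15% fat-fraction design spread, so the fat-fraction column of the
  confounder analysis is not informative at desk scale even though the
  relaxation columns are.
* At the reduced matrix the deep-image-prior generator under-represents
  focal contrast in structures only a few voxels wide: on pathological
  phantom cases whose myocardial properties differ strongly from the
  surrounding tissue, the mapped ring values shrink toward their
  neighbourhood (tens of ms in T1) even though the healthy-case bounds are
  met. This is a resolution effect of the generator's spatial prior, not of
  the encoding model; the direct-gridding reconstruction does not show it.
  At the full 192 matrix the ring is three times wider relative to the
  network's receptive hierarchy and the effect correspondingly smaller.
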