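# rosettecmrf

Simultaneous T1, T2, T2\* and fat-fraction mapping of the heart from a single
rosette cardiac MR fingerprinting (cMRF) scan, reconstructed with a per-scan
deep image prior — implemented end to end in R, with direct-gridding and
iterative locally-low-rank baselines, a full acquisition simulator, and
digital phantoms for validation.

## The problem

Clinical cardiac tissue characterization acquires T1, T2, T2\* and
proton-density fat fraction (PDFF) in separate breathholds, giving
mis-registered maps whose values confound each other. cMRF instead drives the
magnetization through a transient state — here 15 heartbeats of 12 FISP
excitations each (TR 20.4 ms), with inversion and T2-preparation pulses in a
repeating five-beat pattern and a sinusoidal 5.7–20° flip ramp — and matches
each voxel's signal evolution against a Bloch-simulated dictionary. A rosette
readout

> k(t) = kmax · sin(2π ω₁ t/T) · exp(i 2π ω₂ t/T),  ω₁ = 11.5, ω₂ = 7.5, T = 18.4 ms

crosses the k-space origin 24 times per excitation, so every excitation also
yields a 22-echo train (TE₁ 1.74 ms, ΔTE ≈ 0.8 ms) that encodes T2\* decay
and the 220 Hz fat chemical shift, while strongly attenuating off-resonant
fat in gridded images (the decay-weighted 220 Hz response is ≈ 3% of the
on-resonance response).

The pipeline has five stages:

1. **Pre-computation** — EPG dictionary (28 010 T1/T2 pairs on the printed
   grids with T2 ≤ T1) with slice-profile and inversion-efficiency
   corrections, rank-10 SVD subspace, per-echo density compensation,
   off-resonance map (variable-projection search with Markov smoothing) and
   Walsh-style coil maps, all from the cMRF data itself.
2. **Reconstruction** of complex subspace-echo images (10 × 22) by direct
   gridding, regularized iteration, or the deep image prior: an untrained
   convolutional encoder-decoder with skip connections, attention gating and
   7% dropout, optimized for 100 iterations so that its output images are
   consistent with the acquired k-space through the full encoding model
   (coils, static off-resonance phase per echo, rotated rosette sampling).
3. **Dual-exponential T2\* fitting** of the first-subspace echo images
   (water and fat decays, estimates clamped to [2.2, 200] ms).
4. **IDEAL water/fat separation** of the subspace-echo images followed by
   dictionary pattern matching of both components.
5. **PDFF** from the matched spin densities with the magnitude
   discrimination estimator.

## Worked example

Simulate a healthy short-axis phantom and map it with the deep-image-prior
pipeline at the reduced desk scale (matrix 64; a few minutes on one CPU —
use `method = "direct"` for a fast first look):

```r
library(rosettecmrf)

phantom <- make_cardiac_phantom(64, "healthy")
fit <- cmrf_pipeline(phantom = phantom, method = "direct", seed = 1)
print(fit)
#> rosette cMRF fit (direct reconstruction, matrix 64)
#>   region summary (water maps, mean +/- voxelwise SD):
#>    body         T1   1000/ 996.9+-39.6  T2    44/ 44.1+-3.3  T2*   30/ 30.1+-3.3  PDFF  0.0%/ 5.8%
#>    myocardium   T1    950/ 941.8+-30.0  T2    48/ 47.2+-3.2  T2*   30/ 29.7+-2.0  PDFF  1.0%/ 5.6%
#>    rv_blood     T1   1550/1550.4+-34.2  T2   240/251.1+-23.2 T2*   60/ 61.3+-7.7  PDFF  0.0%/ 3.5%
#>    liver        T1    570/ 567.0+-15.8  T2    46/ 46.1+-2.0  T2*   28/ 28.0+-1.6  PDFF  3.0%/ 6.3%
#>    subcut_fat   T1   1000/1295.2+-905.8 T2    40/172.2+-322.3 T2*   30/ 54.1+-75.8 PDFF 90.0%/90.1%
#>    lv_blood     T1   1550/1559.2+-41.2  T2   240/255.2+-28.2 T2*   60/ 61.2+-9.5  PDFF  0.0%/ 3.5%
```

Each row reports true / measured mean ± voxelwise SD inside the tissue (one
pixel eroded). T1, T2 and T2\* recover to a few percent. Two caveats are
visible in this quick direct-gridding look: the voxelwise fat-fraction map
carries a few percentage points of spurious fat (aliasing noise of the
undersampled gridding reconstruction rectifies into the fat channel — the
deep-image-prior method, `method = "dip"`, suppresses it to fractions of a
point), and water-referenced maps in the 90%-fat subcutaneous layer are
dominated by the fat component — the fat maps (`fit$maps$t1_f`, ...) carry
that tissue. `plot(fit)` displays the maps; `coef(fit)` returns per-tissue
means; `roi_pdff()` gives noise-robust regional fat fractions;
`write_cmrf_fit(fit, "out/")` writes NIfTI maps with a JSON provenance
sidecar and the resolved YAML configuration.

The rosette itself:

```r
traj <- rosette_trajectory()
count_origin_crossings(traj)          # 24
response_function(traj, 220)          # 0.0386: fat passes at ~4% amplitude
check_gradient_feasibility(traj)
#> peak |G| = 29.51 mT/m (limit 43.0): PASS
#> peak slew = 165.2 T/m/s (limit 180 T/m/s): PASS
```

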