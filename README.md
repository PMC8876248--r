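# memprobe

Analysis toolkit for small fluorescent probes — rhodamine-type dyes — in
phospholipid (POPC) bilayers. It covers the computational side of a combined
simulation/fluorescence study of membrane partitioning:

1. **Free-energy profiles from umbrella sampling.** Window time series of the
   probe depth *z* (distance of the probe center of mass from the local
   bilayer center of mass) are recombined with the Weighted Histogram
   Analysis Method (WHAM): with bias energies
   c<sub>ib</sub> = k/2 (z<sub>b</sub> − z<sub>ref,i</sub>)² the
   self-consistent equations

   p<sub>b</sub> ∝ Σ<sub>i</sub> n<sub>ib</sub> / Σ<sub>i</sub> N<sub>i</sub> exp((f<sub>i</sub> − c<sub>ib</sub>)/RT),
   f<sub>i</sub> = −RT ln Σ<sub>b</sub> p<sub>b</sub> exp(−c<sub>ib</sub>/RT)

   are iterated to machine tolerance and ΔG(z) = −RT ln p<sub>b</sub> is
   anchored to zero in the water phase. Block-bootstrap error bands,
   time-range convergence scans, and the translocation
   (ΔG(0) − ΔG<sub>min</sub>) and desorption (ΔG(z<sub>max</sub>) −
   ΔG<sub>min</sub>) barriers are provided.

2. **Partition coefficients, two ways.** From a profile,
   K<sub>P</sub> ∝ ∫₀ᵃ exp(−ΔG(z)/RT) dz (a relative quantity; only ratios
   between species are meaningful, normalized via `normalize_kp()`). From
   fluorescence titrations with lipid vesicles, by nonlinear least squares on
   the partition equation

   I<sub>f</sub> = (S<sub>W</sub> + S<sub>M</sub> K<sub>P</sub> V̄ [POPC]) / (1 + K<sub>P</sub> V̄ [POPC]),

   with V̄ = 0.8 dm³/mol the lipid molar volume, followed by geometric-mean
   aggregation of K<sub>P</sub> across replicates with a Student-t interval
   on ln K<sub>P</sub>. Henderson–Hasselbalch bookkeeping of ionization
   states (`species_fractions()`) is included.

3. **Structural descriptors** from bilayer trajectories (multi-frame GRO):
   symmetrized mass density profiles, folded atomic depths, area per lipid,
   united-atom deuterium order parameters −S<sub>CD</sub>, axis tilt
   distributions (xanthene long/short axes, lipid P–N vector) against the
   leaflet-outward normal, geometric hydrogen-bond counts (0.35 nm / 30°),
   and the local-cylinder bilayer center of mass (1.1 nm radius) used by the
   reaction coordinate.

4. **Synthetic data with known ground truth**: overdamped Brownian dynamics
   on analytic free-energy surfaces (flat, harmonic, square well, membrane
   double well) for umbrella windows; a toy bilayer/probe frame generator
   with prescribed depth/orientation/hydrogen-bond statistics; noisy
   titration curves. These stand in for production simulations and wet-lab
   titrations so every analysis route is testable against exact answers.

## Worked example

Sample the canonical 41-window ladder (0–4 nm, 0.1 nm spacing,
k = 3000 kJ mol⁻¹ nm⁻²) on a double-well surface with a 40 kJ/mol well at
1.4 nm and a 25 kJ/mol central barrier, then reconstruct it:

```r
library(memprobe)
surf <- reference_surface("membrane_double_well", D = 40, B = 25, z_min = 1.4)
wins <- sample_window_ladder(surf, n_steps = 1e5, seed = 1)
prof <- solve_wham(build_histograms(wins))
extract_barriers(prof)
#> minimum -40.56 kJ/mol at z = 1.450 nm; translocation 24.07, desorption 40.56 kJ/mol
```

The recovered desorption barrier (40.56) and minimum position (1.45 nm)
match the generating surface (40 at 1.4 nm) to sampling precision; the
translocation barrier (24.07) approaches its true 25 as windows lengthen.

Fit synthetic replicate titrations of a strongly partitioning dye
(K_P = 1.5×10⁴, fluorescence enhanced 5.7-fold in the membrane):

```r
model <- partition_model(S_W = 100, S_M = 570, K_P = 1.5e4)
fits <- lapply(1:5, function(r)
  fit_partition_model(generate_titration(model,
                                         titration_concs(12, 1e-6, 1e-3),
                                         noise_cv = 0.02, seed = r,
                                         replicate_id = paste0("r", r))))
fits[[1]]
#> partition fit (r1, n = 13, converged):
#>             S_W     S_M     K_P
#> estimate 99.080 569.200 15640.0
#> se        2.471   4.874   646.8
aggregate_kp(fits, confidence = 0.90)
#> K_P = 1.57e+04 (IC90% [1.55e+04, 1.6e+04], n = 5 titrations)
```

The per-replicate estimates scatter around the generating truth with ~2%
noise, and the aggregate is the geometric mean with its 90% interval.

`run_pipeline()` chains the stages (simulate → wham → kp → fit-titration →
density/order/tilt/hbond) from a JSON config, writing CSV/XVG/JSON outputs
plus a metadata file; reruns with the same config and seed are
byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch, synthetic titrations at the two dyes' published
best-fit parameters (12 log-spaced lipid concentrations plus zero, 2%
multiplicative noise), refits the partition equation 100 times with derived
seeds, and writes the mean recovered K_P for each dye and the recovered
S_M/S_W signal ratio as JSON.
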