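---
title: "Methods: free-energy profiles, partitioning and bilayer descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy profiles, partitioning and bilayer descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

# The problem

Rhodamine-type dyes partition into phospholipid bilayers, and both the
strength of that partitioning and the probe's depth and orientation in the
membrane govern how the dyes behave as fluorescent reporters and as
transporter substrates. Two experimental windows onto the same physics are
analyzed here: umbrella-sampling simulations that yield a free-energy
profile $\Delta G(z)$ across one bilayer leaflet, and fluorescence
titrations with lipid vesicles that yield a partition coefficient $K_P$.
`memprobe` implements the full analysis chain for both, plus the structural
descriptors used to characterize the inserted probe, with a synthetic-data
layer that provides exact ground truth for every route.

Units are fixed throughout: nm, ps, kJ/mol, K, mol/dm^3. All unit
conversions happen at I/O boundaries only.

# Umbrella sampling and WHAM

## The model

A ladder of windows restrains the probe depth $z$ (probe center of mass
relative to the *local* bilayer center of mass, see below) with harmonic
biases $k/2\,(z - z_{\mathrm{ref},i})^2$. The canonical layout is 41
windows, $z_\mathrm{ref} = 0 \dots 4$ nm spaced 0.1 nm, with
$k = 3000$ kJ mol$^{-1}$ nm$^{-2}$. Window histograms $n_{ib}$ on a shared
grid are recombined self-consistently (WHAM):

$$p_b \propto \frac{\sum_i n_{ib}}{\sum_i N_i \exp((f_i - c_{ib})/RT)},
\qquad
f_i = -RT \ln \sum_b p_b\, e^{-c_{ib}/RT},$$

with $c_{ib}$ the bias energy evaluated at bin centers (the standard WHAM
discretization) and $N_i$ the in-range sample count of window $i$. The
profile is $G(z_b) = -RT\ln p_b$, masked (`NA`) on empty bins.

## Numerical choices

* **Bin width 0.02 nm** over $[0, 4]$ nm: five bins per window spacing, so
  adjacent windows overlap over several bins. With $k = 3000$ the biased
  distribution has sd $\sqrt{RT/k} \approx 0.029$ nm, i.e. 1.5 bins.
* **Convergence**: iterate until $\max_i |\Delta f_i| < 10^{-6}$ kJ/mol
  (default), hard cap $10^5$ iterations with an error reporting the
  residual. The $f_i$ are gauge-fixed to $f_1 = 0$ each iteration.
* **Connectivity**: windows are nodes of an overlap graph (edge = a shared
  populated bin); a disconnected graph is an error naming the components,
  since WHAM cannot stitch disjoint pieces.
* **Anchor**: profiles are shifted so $G = 0$ at the last defined grid
  point ($z = 4$ nm, water). The alternative anchor at the minimum is
  available (`anchor = "min"`); which convention a published profile uses
  is often unstated, and only the anchor-at-water choice makes the
  partition integrand $e^{-G/RT} \approx 1$ in water, which the
  $K_P$ integral requires.
* **One-sided coordinate, no symmetrization.** The umbrella ladder samples
  one leaflet ($z \ge 0$); density profiles, not PMFs, are symmetrized.
* **Ties in the minimum search** break toward smaller $z$, for
  determinism; barriers are translocation $G(0) - G_{\min}$ and desorption
  $G(z_{\max}) - G_{\min}$.

## Uncertainty and convergence diagnostics

`bootstrap_uncertainty()` resamples each window in contiguous time blocks
(with replacement, windows independent), re-solves WHAM per replicate and
reports the pointwise sd. The block length (default one twentieth of the
window span) trades decorrelation against block count; identical input
data produce a zero band, and the band is deterministic given the seed.

`convergence_scan()` re-analyzes sub-ranges of the time series — discarding
initial time, discarding final time, or consecutive blocks — and returns
the barrier series for trend inspection. On stationary data the barrier
versus block regression slope is statistically indistinguishable from zero;
a deliberate drift (e.g. each block sampled from a progressively deeper
surface, emulating unequilibrated windows) yields a slope whose confidence
interval excludes zero. Both behaviours are exercised in the test suite.

# Partition coefficients

## From profiles

$K_P \propto \int_0^a e^{-\Delta G(z)/RT}\, dz$ with $a = 4$ nm; the choice
of $a$ is uncritical because the water-phase integrand is $\approx 1$,
dwarfed by the well contribution. The integral is trapezoidal on the
profile grid; masked interior points are linearly interpolated with a
warning. The proportionality constant is undefined — the output is an
nm-weighted relative quantity, and only ratios (via `normalize_kp()`,
reference species mapping to exactly 1) are compared across species. The
thermodynamically naive $K_P = e^{-\Delta G_{\min}/RT}$ is deliberately not
offered: reference-state ambiguities make the absolute number meaningless.

The square-well surface uses a half-open convention ($G = -D$ on
$[z_{lo}, z_{hi})$). When grid points land exactly on the discontinuities
the trapezoid then integrates the well width exactly, which is what lets
an analytic oracle pin the integral to 0.1%.

## From titrations

The fluorescence of a dye titrated with vesicles follows

$$I_f = \frac{S_W + S_M K_P \bar V [\mathrm{POPC}]}
             {1 + K_P \bar V [\mathrm{POPC}]},$$

a two-state water/membrane partition with $\bar V = 0.8$ dm$^3$/mol held
fixed. `fit_partition_model()` runs nonlinear least squares on
$(S_W, S_M, \ln K_P)$ — the log parameterization keeps $K_P > 0$ — with
data-driven starting values ($S_W$ from the zero-lipid point, $S_M$ from
the highest lipid point, $K_P$ from the mid-rise concentration). Standard
errors come from the Gauss–Newton covariance at the optimum; the $K_P$
error is delta-method from $\ln K_P$. Weights are uniform (no weighting
scheme is prescribed by the assay). `scaleOffset = 1` in the `nls` control
handles the zero-residual limit, so noise-free data converge cleanly to
the exact generating parameters instead of tripping the relative-offset
criterion. Degenerate data with $S_M \approx S_W$ leave $K_P$
unidentifiable; the fit is not silently "fixed" but flagged, through
non-convergence or an exploding relative standard error.

Replicates are aggregated as $\exp(\mathrm{mean}(\ln K_P))$ — the
geometric mean, appropriate for a positive, log-scattered quantity — with
a Student-t interval on $\ln K_P$ at a configurable confidence level
(default 90%). The t-interval is a design choice; the original
interval-construction method for such titrations is not specified in this
package's sources, so the choice is documented and swappable.

Ionization bookkeeping uses sequential Henderson–Hasselbalch transitions;
aqueous p$K_a$ values (7.2 for the Rh123 cation/neutral pair, ~3.2 for the
RhB cation/zwitterion pair) need not reflect the bilayer-inserted
equilibria, so no pH-dependent mixing of profiles is attempted.

# Structural descriptors

* **Density profiles**: per frame, $z$ is re-centered on the lipid center
  of mass; mass histograms divided by bin volume, averaged over frames,
  optionally symmetrized $(\rho(z) + \rho(-z))/2$ (exactly even on the
  grid) and scaled for display. Binned mass is conserved to machine
  precision.
* **Atomic depths**: per-group, per-molecule center-of-mass depth folded by
  $|z|$ (leaflets merged, as depth figures report single positive values);
  mean and sd over frames and molecules.
* **Area per lipid**: $L_x L_y / (n_\mathrm{lipids}/2)$ per frame.
* **Order parameters**: united-atom force fields carry no aliphatic
  hydrogens, so C–H directions are reconstructed from backbone geometry:
  at carbon $i$, with unit bonds $a_1, a_2$ to the neighbours, the two H's
  lie in the plane of the inverted bond bisector and the backbone-plane
  normal at the tetrahedral half-angle (54.74°). $S_{CD} =
  \langle(3\cos^2\theta_{CH} - 1)/2\rangle$ against the bilayer normal,
  reported as $-S_{CD}$; terminal carbons are omitted, and collinear
  backbone triplets (no defined plane) are skipped. An all-trans chain
  along the normal gives exactly $-S_{CD} = 0.5$, an in-plane chain
  $-0.5$, an isotropic ensemble 0 — all verified against constructed
  coordinates.
* **Tilt distributions**: the xanthene long axis is defined as the vector
  through the two amino-bearing ring termini (N1 → N2); the short axis as
  COM(xanthene) → COM(benzoic ring); the lipid headgroup axis as P → N.
  Angles are measured against the *leaflet-outward* normal ($+z$ upper,
  $-z$ lower), which makes a symmetric probe in a symmetric bilayer peak
  at 90° — the convention that matches how such distributions are usually
  plotted; the raw $+z$ convention is available. Densities integrate to 1
  over degrees.
* **Hydrogen bonds**: geometric criterion, donor–acceptor distance
  $\le 0.35$ nm and H–donor–acceptor angle $\le 30°$ (the convention of
  the GROMACS family, since H-bond counts are usually reported without
  stating criteria). Hydrogens attach to declared donors by proximity in
  the first frame; each H binds at most the single closest qualifying
  acceptor per frame; intramolecular pairs are excluded; distances use
  the minimum image. Partners are classed as lipid oxygen (by atom name),
  water, or other probe.
* **Local bilayer center**: the reaction-coordinate reference is the COM
  $z$ of lipids whose in-plane COM lies within a 1.1 nm cylinder of the
  probe (minimum image), which decouples the coordinate from long-range
  bilayer undulations. An empty cylinder is an error suggesting a larger
  radius.

# The synthetic-data layer

## What it emulates

* **Umbrella windows**: overdamped (Brownian) Langevin dynamics on an
  analytic surface plus bias,
  $z \leftarrow z - D\,U'(z)\,\Delta t/RT + \sqrt{2 D \Delta t}\,\xi$.
  Overdamped rather than inertial dynamics is a deliberate choice: WHAM
  only consumes stationary statistics, and the overdamped sampler has the
  simple stability contract $a = k D \Delta t / RT < 0.1$ (enforced with
  an error). The Euler scheme inflates the stationary variance by
  $1/(1 - a/2)$, so the defaults keep $a \approx 0.02$ (1% bias):
  $D = 5\times10^{-4}$ nm$^2$/ps, a realistic in-bilayer small-molecule
  diffusivity, and $\Delta t = 0.033$ ps. The first 10% of steps are
  discarded as burn-in, mirroring the practice of dropping early window
  time before analysis. With these defaults the relaxation time in a
  $k = 3000$ window is $RT/(kD) \approx 1.7$ ps ($\approx 50$ steps), so
  a $2\times10^5$-step window carries roughly $4\times10^3$ effectively
  independent samples.
* **The `membrane_double_well` surface** is the stand-in for a probe PMF:
  minima of depth $D$ at $\pm z_{\min}$, central barrier $B$ above the
  minima, zero in water, joined by zero-slope cubic segments. Its barrier
  parameters ($D = 40$, $B = 25$ kJ/mol, $z_{\min} = 1.4$ nm as the
  canonical test case) sit in the published range for such dyes, and are
  recovered by the full 41-window pipeline within 1.5 kJ/mol in the
  acceptance tests.
* **Toy bilayer frames**: pseudo-atoms with realistic names and masses but
  no bonded physics — the descriptors only need geometry. Headgroup atoms
  at Gaussian depths (P at 1.88 ± 0.10 nm), an all-trans zigzag sn-1 chain
  along a tilted director, rigid probe templates placed at Gaussian depth
  (1.5 ± 0.4 nm per leaflet, the published probe-COM scale) with a
  configurable long-axis orientation law, and a water slab whose first
  molecules double as hydrogen-bond contact partners placed at ideal donor
  geometry with a set rate. How probes distribute between leaflets is
  exposed as a parameter (`probe_leaflets`) because the emulated systems
  leave it unspecified; the default alternates.
* **Titrations**: the partition equation evaluated at log-spaced lipid
  concentrations plus a zero point, with multiplicative Gaussian noise
  ($I = I_{\mathrm{model}}(1 + \mathrm{cv}\,\xi)$) — fluorescence error
  scales with signal. The default 2% cv reflects a well-run plate-reader
  titration.

## What it does not emulate

No force field, water model, or electrostatics; no attempt to reproduce
POPC material properties from first principles; frames are independent
draws, not a correlated trajectory; probe conformational flexibility is
absent (rigid template). A green test therefore establishes that the
*analysis* is correct against known ground truth — not that any particular
simulation result is right. Degrees of sampling correlation, force-field
error and finite-size effects in real data are outside what these tests
can certify.

# Known limitations

* WHAM only — no MBAR or umbrella-integration estimators, no 2-D reaction
  coordinates, no automatic window placement.
* Trajectories are read as multi-frame GRO; compressed binary trajectory
  formats are not parsed (no suitable reader in the supported dependency
  set), so production trajectories must be exported to GRO frames first.
* The WHAM self-consistency iteration is plain fixed-point; for badly
  overlapping ladders it converges slowly (the iteration cap and residual
  error make this loud rather than silent).
* The bootstrap resamples whole blocks within windows; it does not model
  between-replicate (independent-ladder) variability.
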