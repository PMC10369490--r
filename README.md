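# phrex

Post-processing for pH replica-exchange (pHRE) constant-pH molecular
dynamics of membrane-inserting peptides — the pHLIP family and its
arginine variants in particular — plus the experimental-side fitting
used alongside such simulations.

A pH-low insertion peptide crosses a lipid bilayer only when its key
aspartate protonates, and that residue's pKa shifts as it buries into
the membrane. `phrex` turns per-frame simulation records (replicate,
replica, pH, time, insertion depth, binary protonation, shell counts)
into:

- **pKa-versus-depth profiles**: frames sliced into 0.5 Å insertion
  bins, per-bin titration curves screened by three quality-control
  criteria (≥ 10 points of each protonation state per replicate and pH;
  ≥ 3 replicates spanning ≥ 2 replicas; pooled-curve monotonicity within
  0.05), fit with the Hill model
  `f(pH) = 1 / (1 + 10^{n (pH − pKa)})`, with Bayesian-bootstrap error
  bars and a deep-window summary `pKa_ins`;
- **membrane geometry**: signed insertion depth against a local
  phosphate-surface reference (6 Å / 10-atom support), annulus
  half-thickness deformation scans, TM tilt angles;
- **interaction-shell censuses**: phosphate/choline contacts at the
  5.2 Å first-shell cutoff, Asp–Arg salt bridges (4.0 Å), water hydrogen
  bonds (3.5 Å / 30°);
- **the pHRE exchange criterion**
  `p = min{1, 10^{(pH_m − pH_l)(x_i − x_j)}}`, with ledger bookkeeping
  and a toy ladder simulator for exchange-efficiency studies;
- **experimental fits**: Hill fits of normalized pH-dependence data and
  multiexponential stopped-flow fits
  `I(t) = c + Σ a_i exp(−t/τ_i)` with the reduced-χ² < 3×10⁻⁵ /
  factor-of-10 term-selection rule;
- **feature attribution**: shell properties interpolated at each bin's
  pKa and ranked by a random-forest regressor (2500 trees, depth 20).

A first-class synthetic-data module generates every input with known
ground truth (Hill protonation sampling over a depth-dependent pKa
profile, exchange-mixed replicas, deformable phosphate lattices,
kinetic traces), so the entire pipeline is validated by parameter
recovery. See the methods vignette
(`vignettes/membrane-pka-profiling.Rmd`) for the models, assumptions
and design choices.

## Worked example

Recover a desolvation-like ground truth (pKa rising 6.0 → 7.0 over the
first 6 Å of insertion) from synthetic pHRE frames at production scale
(5 replicates × 4 pH replicas × 20 000 frames, pH 5.00–7.25 in 0.75
steps):

```r
library(phrex)
zc    <- seq(-7, 1, 0.5)
truth <- ground_truth_profile(zc, 6.0 + pmin(pmax(-zc / 6, 0), 1))
cfg    <- synthetic_config(n_replicates = 5, n_frames = 20000, seed = 1)
frames <- generate_phre_frames(truth, cfg)
prof   <- build_profile(frames, n_boot = 1000, seed = 1)
subset(prof, pass,
       select = c(bin_low, bin_high, pka, hill_n, bootstrap_sd, n_frames))
```

```
 bin_low bin_high  pka hill_n bootstrap_sd n_frames
    -5.5     -5.0 6.88  1.007      0.00960    22192
    -5.0     -4.5 6.78  1.027      0.00822    21820
    -4.5     -4.0 6.71  0.997      0.00621    21100
    -4.0     -3.5 6.63  1.022      0.00816    21125
    -3.5     -3.0 6.54  1.009      0.00979    21010
    -3.0     -2.5 6.45  0.997      0.00907    21144
    -2.5     -2.0 6.37  1.000      0.00821    21549
    -2.0     -1.5 6.30  0.995      0.00735    21834
    -1.5     -1.0 6.22  1.001      0.00749    21401
    -1.0     -0.5 6.11  0.979      0.00871    21350
    -0.5      0.0 6.04  0.994      0.00837    21430
     0.0      0.5 5.98  0.954      0.01609    10641
```

The fitted profile climbs ~0.15 pKa units per 1 Å of insertion with
bootstrap errors of ~0.01, tracking the imposed truth; bins whose
sampling violates a quality-control criterion (here the deepest and
shallowest extremes) carry flags instead of estimates. The deep-window
summary `pka_ins(prof)` gives 6.88 over [−6, −5] Å. The same session
fits a three-phase kinetic trace built from published-scale time
constants:

```r
tr <- generate_kinetic_trace(c(0.5, 0.3, 0.2), c(0.009, 1.8, 27),
                             offset = 0.2,
                             t_grid = 10^seq(-3, 2.3, length.out = 400))
fit_multiexponential(tr)[c("N", "taus")]
#> selected N = 3, taus = 0.009, 1.8, 27 s
```

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

1. `01_simulate.R` — synthetic inputs for all presets;
2. `02_geometry_census.R` — surface reference, dimple deformation scan,
   shell census;
3. `03_pka_profiles.R` — profile recovery for the upward and inverted
   scenarios, with QC and bootstrap errors;
4. `04_experimental_fits.R` — Hill and multiexponential fit tables;
5. `05_attribution.R` — cross-variant feature matrix and forest
   importances.

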