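# paintquant

Absolute quantification of binder labeling efficiency — and
labeling-efficiency-corrected protein dimerization — from two-channel
single-molecule localization microscopy data (DNA-PAINT / Exchange-PAINT).

## Who this is for

Anyone using affinity binders (nanobodies, antibodies, affibodies) to
label proteins for super-resolution imaging and needing to know what
fraction of target molecules the binder actually hit. Incomplete labeling
silently biases every downstream count: apparent cluster stoichiometries,
oligomer fractions and copy numbers are all too low by an amount that
differs between binders and protocols.

## The method

A molecular construct carries a **reference tag** and the **target**
epitope of interest; both are labeled and imaged in separate channels at
single-protein resolution. Among constructs with a detected reference,
the labeling efficiency of the target binder is

```
LE = N_RefTarget / (N_Ref + N_RefTarget)
```

independent of the reference binder's own efficiency. Since molecules
cannot be paired one-by-one at realistic densities, the pairing is
statistical: the package computes, for each reference molecule, the
**cross nearest-neighbor distance (NND)** to the closest target molecule,
then fits the NND histogram with simulated mixtures of two populations —
complete-spatial-randomness (CSR) monomers plus "dimers" (constructs with
both labels, partners separated by the binder-geometry offset `d_off` and
blurred by the positional uncertainty σ). Candidate LE values are scanned
on a grid; density matching pins the simulated channel densities to the
measured ones, and the least-squares candidate over the binned NND
densities wins.

The same machinery runs in reverse for oligomerization: a single
channel's **self-NND** histogram is fitted with thinned monomer/dimer
simulations under the constraint
`(rho_mono + 2*rho_dimer) * LE = rho_observed`, giving a dimer fraction
*corrected* for the measured labeling efficiency (fitting with LE = 1
yields the biased *apparent* fraction). Group comparisons use a
two-sided bootstrap ratio test and percentile bootstrap confidence
intervals.

Pipeline stages, each an exported function:

1. `read_localizations()` — Picasso-style HDF5 (`locs` dataset) or CSV, pixel-to-nm conversion
2. `cluster_localizations()` + `molecules_from_clusters()` — localization clouds → precision-weighted molecule centers
3. `cross_nnd()` / `self_nnd()` + `histogram_nnd()` — distance statistics
4. `fit_labeling_efficiency()` / `fit_dimer_fraction()` + `correct_dimer_fraction()` — Monte-Carlo least-squares fits
5. `bootstrap_ci()`, `bootstrap_ratio_test()` — per-cell statistics

A synthetic-data generator (`fixture_config()`, `generate_ground_truth()`,
`generate_localizations()`, `write_fixture()`) produces DNA-PAINT-like
localization tables with known ground truth, so the whole chain is
testable without any experimental download.

## Worked example

Simulate a ground-truth field at true LE = 0.5 (monomer densities
5 µm⁻², dimer density 5 µm⁻², `d_off` = 15 nm, σ = 5 nm, 10×10 µm ROI),
emit localization tables, and run the full pipeline:

```r
library(paintquant)

roi <- roi_rect(0, 0, 10000, 10000)
cfg <- fixture_config(
  sim_params(roi, rho_ref_mono = 5, rho_target_mono = 5, rho_dimer = 5,
             d_off = 15, uncertainty = 5, seed = 7),
  mean_locs_per_molecule = 20, seed = 7)
paths <- write_fixture(cfg, "demo")

ref_locs <- read_localizations(paths$reference)
ref <- molecules_from_clusters(
  ref_locs, cluster_localizations(ref_locs, radius = 12, min_locs = 5), roi = roi)
ref
#> <molecule_set: 1067 molecules, 100.0 um^2 ROI, 10.67 um^-2>

tgt_locs <- read_localizations(paths$target)
tgt <- molecules_from_clusters(
  tgt_locs, cluster_localizations(tgt_locs, radius = 12, min_locs = 5), roi = roi)

h <- histogram_nnd(cross_nnd(ref, tgt))
fit <- fit_labeling_efficiency(h, binder_density(ref), binder_density(tgt),
                               d_off = 15, uncertainty = 5, roi = roi,
                               config = fit_config(seed = 11))
fit
#> <le_fit: labeling efficiency 0.480 (grid max 0.932, rss 7.48e-06, 20 realizations)>
```

The fitted LE of **0.480** recovers the true 0.5 to within the grid and
Monte-Carlo resolution at this sample size (~1000 reference molecules;
larger ROIs tighten it — the acceptance suite demonstrates mean absolute
error < 0.05 at ≥ 2000 molecules). `fit$residual_curve` holds the full
residual-vs-candidate curve; a sound fit has a single clear minimum
there. Per-cell LE estimates aggregate with

```r
bootstrap_ci(c(0.48, 0.52, 0.50, 0.47, 0.55, 0.51), seed = 1)
#>   low  high
#> 0.485 0.527
```

The same steps are scriptable via the installed CLI
(`exec/paintquant`): subcommands `cluster`, `fixtures`, `nnd`, `fit-le`,
`fit-dimer`, `specificity`, `ratio-test`; every stochastic command takes
`--seed` and records it in its output.

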