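---
title: "Quantifying absolute labeling efficiency from two-channel localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying absolute labeling efficiency from two-channel localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paintquant)
```

## The problem

Super-resolution methods such as DNA-PAINT resolve individual protein
copies, but every quantitative statement about protein numbers,
stoichiometry or oligomerization rests on knowing which fraction of target
molecules actually carried a detectable binder. Nanobodies and antibodies
never label 100% of their targets — affinity, steric hindrance and
fixation artifacts all cost signal — and the miss rate differs between
binders, conjugation chemistries and protocols.

`paintquant` implements a reference-tag strategy for measuring that miss
rate absolutely. A construct carries both a reference tag and the target
epitope; after staining, the sample contains constructs with only the
reference labeled, only the target labeled, or both. Among the
reference-positive constructs, the labeling efficiency (LE) of the target
binder is

$$\mathrm{LE} \;=\; \frac{N_{\mathrm{Ref+Target}}}{N_{\mathrm{Ref}} + N_{\mathrm{Ref+Target}}},$$

which does not depend on the reference binder's own efficiency (an
unlabeled reference removes a construct from both numerator and
denominator).

Because molecules cannot be paired construct-by-construct at realistic
densities, the assignment is statistical: for every reference molecule we
compute the cross nearest-neighbor distance (NND) to the closest target
molecule. Constructs with both labels contribute a short-distance mode
centered near the lateral binder offset $d_\mathrm{off}$, broadened by the
positional uncertainty; reference-only constructs contribute the
long-distance background expected from an unrelated target field. The LE
is read off by fitting the measured NND histogram with simulated mixtures
of the two populations.

## The forward model

All fits compare data against explicit simulations in the same ROI:

* **Monomers** are complete spatial randomness (CSR): counts are
  Poisson(density x area), positions uniform in the ROI.
* **Dimers** (constructs with both labels, or true protein dimers) are CSR
  centers; the two partners sit at $\pm d_\mathrm{off}/2$ from the center
  along a uniformly random orientation, so the pre-noise separation is
  exactly $d_\mathrm{off}$. The wording "a distance with expected value
  $d_\mathrm{off}$" admits a random-separation reading; we chose the exact
  separation as the simplest model consistent with it — the Gaussian
  positional noise spreads the observed separations anyway.
* **Positional uncertainty** is an isotropic Gaussian displacement of
  every molecule (per-axis $\sigma$), summarizing localization error,
  cluster-center error and linkage flexibility.
* **Detection thinning** (single-channel model only) keeps each molecule
  independently with probability LE.

Boundary rule: dimer centers are drawn inside the ROI and partners may
land slightly outside; they are retained rather than clipped, so edge
effects match experimental data analyzed in the same ROI. The same reason
dictates that no analytical edge correction is applied to NNDs — the bias
is identical in data and simulation by construction.

The density convention for dimers is *entities*: a field with monomer
density $\rho_m$ and dimer density $\rho_d$ contains $\rho_m + 2\rho_d$
molecules per unit area, and the observed single-channel density under
labeling efficiency LE is $(\rho_m + 2\rho_d)\cdot\mathrm{LE}$. The
molecule-count reading of the same relation is ambiguous in common usage;
the entity convention is declared here once and used consistently. Both
conventions of the fitted "dimer fraction" are reported:
`dimer_fraction` $= 2\rho_d/(\rho_m + 2\rho_d)$ (fraction of molecules
residing in dimers, the default) and `dimer_fraction_entities`
$= \rho_d/(\rho_m+\rho_d)$.

## The two fits

**Labeling efficiency** (`fit_labeling_efficiency`). Candidate LE values
are scanned over a grid on $[0, \mathrm{LE}_{\max}]$ with
$\mathrm{LE}_{\max} = \min(1, \rho_\mathrm{target}/\rho_\mathrm{ref})$.
Density matching removes all remaining freedom: each candidate sets
$\rho_\mathrm{dimer} = \mathrm{LE}\cdot\rho_\mathrm{ref}$ and assigns the
rest of each channel's observed density to its monomer population, so
simulated channel densities always equal the measured ones. The candidate
minimizing the summed squared difference between the experimental and the
mean simulated cross-NND *density* histograms wins. Least squares acts on
normalized densities, not counts, so the objective is insensitive to the
(matched) total counts and histogram binning granularity.

**Dimer fraction** (`fit_dimer_fraction`). For one protein species imaged
in one channel, candidate molecule-dimer-fractions $f$ are scanned on
$[0,1]$; the observed-density constraint
$(\rho_m + 2\rho_d)\cdot \mathrm{LE} = \rho_\mathrm{obs}$ then fixes
$\rho_m, \rho_d$. Simulated fields are thinned at LE before self-NNDs are
computed. Fitting with LE forced to 1 yields the *apparent* fraction;
re-fitting with the measured LE (`correct_dimer_fraction`) yields the
*corrected* fraction. Thinning removes dimer partners independently, so
apparent fractions are biased low and increase with the binder's LE,
while corrected fractions are LE-invariant — the package's acceptance
suite verifies exactly this behavior on synthetic ground truth.

## Numerical choices

* **Grid search, not local optimization.** The objective is Monte-Carlo
  noisy and one-dimensional; a global scan (default step 0.01) cannot be
  trapped, and the full residual curve is returned so a pathological fit
  is visible, never silent. Optional parabolic refinement
  (`fit_config(refine = TRUE)`) interpolates the vertex from the argmin's
  neighbors; it is off by default so the reported estimate is exactly the
  minimum of the reported curve.
* **Common random numbers.** Realization $i$ of every candidate uses seed
  `seed + i`, so candidates see correlated noise, the residual curve is
  smooth, and the argmin is deterministic given the seed.
* **Averaging.** Simulated histograms are averaged over
  `n_realizations` (default 20) before the residual is formed.
* **Fit range.** Residuals use bins up to `d_max_nm` (default 500 nm);
  the far tail only carries density information that is matched by
  construction, and including it would dilute the informative
  short-distance contrast.
* **Binning.** Default 10 nm bins from 0 to 1000 nm. Distances beyond the
  last edge accumulate in a recorded overflow mass so total probability
  is 1.
* **Degenerate simulations.** A candidate realization with an empty
  channel (possible at near-zero densities) contributes an all-zero
  density histogram rather than an error.

## Clustering localizations into molecules

DNA-PAINT produces a cloud of localizations per docking site.
`cluster_localizations` counts neighbors within `radius` for every
localization; local maxima of that count become seeds, every localization
within `radius` of a seed joins its nearest seed, and clusters below
`min_locs` members dissolve into noise. Ties between equal neighbor
counts break by lexicographic (x, y) position — a deterministic rule that
is also invariant to the order of rows in the input file, which a
row-index tie-break would not be. Molecule centers are inverse-variance
weighted means (weights $1/\sigma_i^2$ from the per-localization
precisions), with the standard error of the weighted mean as the center
uncertainty (root mean square over the two axes).

Defaults: `radius` ≈ 3x the mean localization precision and
`min_locs = 10`. These are configuration, not reproduction — the
reference workflow's per-experiment values are not published — so any
quantitative claim should state them. The optional `frame_spread_check`
discards clusters whose member frames concentrate in under 20% of the
acquisition (inter-quartile range), a signature of transient sticking
rather than repeated imager binding; it is off by default.

The default "cell area" ROI is the bounding rectangle of the
reference-channel molecules; polygon masks can be supplied where an
actual cell outline exists. Densities are counts over ROI area.

## What the synthetic generator does and does not emulate

`fixture_config`/`generate_localizations` produce localization tables
with: truncated-Poisson (>= 1) localizations per molecule, lognormal
per-localization precisions (default mean 4 nm, sd 1 nm, typical for
high-quality DNA-PAINT), Gaussian scatter of each localization at its own
precision, and uniform frames. Default molecule densities in tests
(5–30 µm⁻²) and $d_\mathrm{off} = 15$ nm with $\sigma = 5$ nm bracket the
membrane-protein regime the assay is designed for.

Not modeled: binding kinetics, multi-frame blinking correlations, camera
noise, photophysics, z. Truncating localization counts at 1 makes every
ground-truth molecule detectable in principle; detection failure is
modeled exclusively by `thin_by_detection`, which keeps the two effects
separable in tests. Consequently a green recovery test establishes that
the estimator chain is unbiased on data satisfying the forward model; it
does not establish robustness to kinetic artifacts, drift residuals or
mis-set $d_\mathrm{off}$ — those must be controlled experimentally.

## Bootstrap statistics

Per-cell estimates are compared between groups with a two-sided bootstrap
ratio test: both groups are resampled with replacement (resampling unit =
cell). The default construction is a *studentized* (bootstrap-t) test of
the log ratio of means: each resample's centered log ratio is divided by
its own delta-method standard error and $p = \Pr(|t^*| \ge |t_{obs}|)$
with a +1 continuity correction, so p is never exactly 0. We initially
implemented the plain percentile form,
$2\min(\Pr[\bar A^*/\bar B^* \le 1], \Pr[\bar A^*/\bar B^* \ge 1])$, but
calibration simulations at the per-cell sample sizes this assay produces
(n ≈ 7 cells per group) showed it over-rejects (type-I ≈ 0.10 at nominal
0.05, a known small-sample deficiency of unstudentized bootstrap tests);
the studentized form measures ≈ 0.046 in the same simulation, which the
test suite asserts. The percentile and basic-bootstrap log-ratio forms
remain available via `pivot = "ratio"` / `"log_ratio"`. The name
"bootstrap ratio test" alone does not fix a construction; the one here is
this package's definition. Confidence intervals are percentile bootstrap
intervals of the mean. Defaults: 10,000 resamples, explicit seed
required by the CLI. Type-I error at nominal 0.05 is verified to lie in
[0.02, 0.08] on null simulations in the test suite. No multiple-testing
correction is applied; comparisons are pairwise by design.

## Known limitations

* Higher-order oligomers (trimers and beyond) are outside the mixture
  model; a genuinely trimeric sample will bias the dimer fraction.
* $d_\mathrm{off}$ and the positional uncertainty are user inputs per
  construct, not fitted; a badly wrong $d_\mathrm{off}$ shifts the
  short-distance mode and biases LE.
* Per-cell fitting is the default convention; pooling NNDs across cells
  before fitting is possible but changes the meaning of the bootstrap
  (the resampling unit stays the cell).
* 2D only; membrane geometry is assumed flat within the ROI.
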