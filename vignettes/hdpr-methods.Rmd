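---
title: "Estimating partial 13C incorporation from peptide mass lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating partial 13C incorporation from peptide mass lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A tryptic peptide is built from the 20 canonical residues plus one
water, so its monoisotopic mass is a nearly fixed blend of C, H, N, O
and S. Hydrogen is the only element whose monoisotopic mass deviates
appreciably (upward) from an integer per unit of nominal mass, and its
share of peptide matter is narrow; the fractional part of the mass (the
*decimal residual* `D_R`) therefore grows almost linearly with the mass
`P_M` itself — the half decimal place rule. Over 300–6,000 Da the
residual of unlabeled peptides climbs at roughly 5e-4 Da per Da,
wrapping past 1 about every 1,900 Da, so the (`P_M`, `D_R`) scatter of a
whole digest forms parallel diagonal bands.

Metabolic ¹³C labeling replaces ¹²C atoms with ¹³C, adding exactly
1.003355 Da per substituted carbon — 0.003355 Da of *residual* per
carbon. Since carbon count is itself nearly proportional to mass
(~0.044 carbons per Da), labeling steepens the residual-vs-mass slope
in proportion to the atom % ¹³C incorporated. That single observation
turns an unidentified mass list into a labeling assay:

1. calibrate slopes `b_12C` (0 atom %) and `b_13C` (100 atom %) on an
   in-silico digested proteome;
2. fit the user mass list's slope `b_user`;
3. interpolate: `atom % = (b_user − b_12C) / (b_13C − b_12C) × 100`.

Step 3 assumes the slope is linear in incorporation. It is very nearly
so, but not exactly: the slope at an intermediate level `p` is a ratio
`(b_12C + p·0.003355·α/100) / (1 + p·1.003355·α/100)` with α the
carbon-per-Da ratio, which sags mid-range by about 1 % of the
calibration span. Package estimates at intermediate truths consequently
carry a small positive bias (about +1 atom % near 50 atom % under the
default synthetic conditions, as the interpolation-linearity test in
`test-incorporation.R` quantifies); correcting it would require assuming
a carbon density, which the method deliberately avoids.

## Band classification and unwrapping

Unwrapping requires knowing which band each point belongs to. Direct
clustering on mass fails near the wrap points, so masses are first
transformed:

    P_M_trans = P_M − k_t · D_R ,     k_t = 1800 Da .

Points with residuals near 0 barely move while points near 1 shift by
almost the full constant, rotating each band into a near-vertical
cluster. The constant 1,800 sits where unlabeled bands become maximally
vertical; larger values tilt them the opposite way. It is a fixed
parameter, not fitted per dataset.

The transformed values are clustered by one-dimensional k-means
(Hartigan–Wong), seeded at preset centers: `0, 2000, 4000` Da for
unlabeled data and `0, 1600, 3200, 4800` Da for fully labeled data over
the default mass window (`band_centers()` derives analogous presets for
any slope). Seeding is deterministic — a single initialisation at the
presets, no random restarts — so calibration is reproducible bit for
bit. Cluster labels are re-ordered by final center position and the
band index is added to the residual in Daltons.

Small mass lists can leave a preset center without any point, which
k-means rejects; one dummy point per center is therefore added before
clustering and removed again before any fitting (`add_dummy_points`,
default on for user data). On well-populated data the dummies do not
change the fitted slope (tested to ~1e-9).

For partially labeled user data the band layout is unknown in advance,
so classification is run at both reference center sets and the
unwrapping with the smaller least-squares error sum of squares is kept.
Ground-truth band assignment (for validation) is defined as the integer
`k` minimising `|D_R + k − b_true·P_M|`; on 50,000-peptide synthetic
references the classifier misassigns on the order of 0.003 % of points
(recomputed by `scripts/acceptance.R`), with errors confined to the
dispersed high-mass band boundaries.

## Slope fitting

The model is `D_R = b·P_M` with the intercept forced to zero — an
unlabeled peptide of vanishing mass has vanishing residual. For large
reference sets the exact least-squares solution
`b = Σ D_R·P_M / Σ P_M²` is used (it matches brute-force SSE
minimisation to 1e-9 in the test oracles). Its standard error uses the
residual variance on `n − 1` degrees of freedom.

User mass lists are small and outlier-prone (contaminant masses,
mis-deconvoluted charge states), and least squares has a breakdown
point of zero. The package therefore fits user data by zero-intercept
M-estimation via iteratively re-weighted least squares: Huber weights
(tuning constant 1.345, ~95 % Gaussian efficiency), scale re-estimated
each iteration as `median(|residual|)/0.6745`, iterated until the
relative slope change drops below 1e-8 or 50 iterations (the fit is
then flagged non-converged rather than silently accepted). Tukey
bisquare weighting is available behind the `psi` argument for data with
very gross outliers. The implementation agrees with the classical IWLS
reference implementation (`MASS::rlm`, Huber/MAD) to ~1e-9 on
contaminated test data, and perturbing 10 % of 100 points by gross
errors moves the slope by far less than 10 % of the calibration span,
while 60 % contamination breaks it — the expected behaviour of an
estimator with breakdown near 0.5.

One consequence of using different estimators for calibration (least
squares) and user data (robust) is a small estimator-mismatch offset:
the residual cloud is heteroscedastic (spread grows with mass) and
slightly asymmetric, so the robust slope of the *reference's own* mass
set differs from its least-squares slope by a few tenths of an atom %
after interpolation. Feeding the reference's light and heavy sets
through the full user pipeline recovers 0 and 100 atom % within
0.5 atom % (asserted in the acceptance tests); calibrating both anchors
with the same least-squares estimator keeps that mismatch from
cancelling only partially at intermediate levels.

## Masses at partial incorporation

The carbon-count formulation makes any labeling level computable by
element counting: `mass(p) = Σ element masses + (p/100)·C·1.003355`.
For *simulated measurements*, however, the package substitutes a whole
number of carbons per peptide, `round(p/100·C)`, rather than the
continuous interpolation. A real deconvoluted measurement reports the
apex of the isotopologue envelope, which always sits an integer number
of 1.003355 Da shifts above the light monoisotopic mass; the continuous
formula instead places every odd-carbon peptide half a Dalton off in
residual at 50 atom %, splitting the point cloud into two interleaved
lattices that integer-Dalton unwrapping cannot reconcile (estimates
then diverge wildly). The continuous mode remains available in
`labeled_masses(mode = "continuous")` for mass arithmetic, and
`monoisotopic_mass()` itself is exactly linear in incorporation.

## The synthetic generator

`generate_synthetic_peptides()` emulates a curated tryptic reference
set: residues drawn from Swiss-Prot average amino-acid frequencies, a
forced K/R C-terminus, lengths 2–40, light masses 300–6,000 Da,
rejection sampling until the filters pass, fully deterministic under a
seed. Two length distributions are offered:

* `"uniform"` (default): lengths flat over 2–40. This emulates a
  reference table that represents all peptide lengths well — the
  situation after the score-based curation steps of in-silico digest
  tools, which discard most of the very short fragments that dominate a
  raw digest. Its calibration slope (~5.21e-4) falls in the expected
  range for curated tryptic references.
* `"tryptic"`: geometric fragment lengths (cleavage probability = the
  combined K/R background frequency), i.e. a raw uncurated digest. The
  abundance of short, K/R-dominated fragments raises the calibration
  slope to ~5.28e-4 and roughly doubles the spread of incorporation
  estimates at a given peptide count, because the mass leverage `Σ P_M²`
  of a draw is much smaller.

What the generator does *not* model: organism-specific amino-acid
composition (a real proteome's slope differs at the 1e-6–1e-5 level —
recalibrate on the matching proteome rather than reusing slopes across
organisms), measurement noise (a ppm-scale Gaussian error option exists
but is off by default), missed cleavages, modifications, and
contaminant non-peptide masses. Passing simulation tests therefore
demonstrate the correctness and internal consistency of the pipeline
under clean conditions, not robustness to instrument artefacts — the
robust fitter's contamination tests cover that aspect separately.

## The accuracy experiment

`accuracy_experiment()` quantifies estimation error versus peptide
count: for each known truth (0, 50, 100 atom %) and subsample size,
draw peptides without replacement, compute exact labeled masses, run
the full estimation pipeline, repeat 100 times. Per cell it reports the
replicate median, quartiles and 2.5–97.5 percentile envelope. The
default error metric is the envelope half-width around the truth — a
whisker-style reading of worst-case single-estimate error; the
parametric 95 % confidence half-width of the median is reported
alongside (it is an order of magnitude narrower and answers a different
question). Under the default conditions (50,000-peptide uniform-length
reference; sizes 60 and 100; the problem sizes `scripts/acceptance.R`
runs) the envelope half-width is roughly 9–11 atom % at 60 masses and
7–8 atom % at 100, plateauing between 200 and 500 masses; the median is
unbiased at the anchors and carries the ~+1 atom % interpolation bias
mid-range.

## Numerical and design choices

* **m/z convention**: z = 1 throughout; input masses are treated as
  neutral singly-charged deconvoluted masses, with no proton-adduct
  arithmetic.
* **Duplicates**: peptides occurring in several proteins stay as
  separate reference entries (entry-level, not unique-sequence,
  bookkeeping).
* **Trypsin rule**: cleave after K/R except before P; protein
  N-terminal methionine is not stripped; no missed cleavages by
  default.
* **Filters**: lengths 2–40 residues, light mass 300–6,000 Da. A
  score-based curation of digest products (as some digest tools apply)
  is intentionally not reproduced — it is tool-internal and not
  portable; the explicit length/mass filters are.
* **Ties and degeneracies**: k-means ties are broken by the clustering
  seed order (lower center first); an all-identical mass list is
  rejected as degenerate; fewer than 3 masses are refused; a perfectly
  colinear robust fit short-circuits with uniform weights (off-line
  points get weight 0).
* **Out-of-range estimates** (slightly below 0 or above 100 atom %) are
  reported with a flag, never clipped — they are diagnostic of noise or
  calibration mismatch.
* **Reporting precision**: slopes are displayed to 6 significant
  digits; all serialisation (reference models, mass lists, tables) uses
  full `%.17g` precision so round-trips are bit-exact.

## Known limitations

* Carbon only: ¹⁵N or ²H labeling changes residuals differently and is
  out of scope.
* The interpolation bias (~1 atom % mid-range) and the
  estimator-mismatch offset (tenths of an atom %) are inherent to the
  published formulation; both are small against the single-estimate
  spread at realistic peptide counts.
* Heteroscedasticity is not modelled: high-mass points are noisier but
  not down-weighted beyond what the robust loss does implicitly.
* Mixtures are averaged: a community whose members label at different
  levels yields one aggregate slope, not a decomposition.
* Below ~60 masses, single estimates can be tens of atom % off; the
  standard error reported with each estimate should be taken seriously.
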