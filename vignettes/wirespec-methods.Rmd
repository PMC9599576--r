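---
title: "Methods: spectral analysis along single-nanowire SERS probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral analysis along single-nanowire SERS probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wirespec)
```

## The measurement this package models

A SERS-active silver nanowire long enough to thread several cells is
scanned by a confocal Raman microscope at 1 µm steps. Each position
yields one spectrum over the 717–1827 cm⁻¹ fingerprint window, sampled at
1015 features (the instrument's native spacing is not part of the
contract; the default grid is simply 1015 equally spaced points over the
closed window, ≈1.096 cm⁻¹ apart). Two kinds of questions are asked of
such data:

1. *Discrimination*: do spectra from a monolayer culture ("2D") and a
   spheroid culture ("3D") differ systematically, and at which bands?
2. *Mapping*: along one wire, which positions are protein-rich and which
   nucleic-acid-rich?

No public raw dataset accompanies this problem, so the package ships a
synthetic generator that is itself first-class, tested code; every
downstream claim is validated against its ground truth.

## Synthetic spectra: the stated world

A clean spectrum is a sum of Lorentzian bands,
$A\,\gamma^2/((\nu-\nu_0)^2+\gamma^2)$ with $\gamma = \mathrm{FWHM}/2$.
Lorentzian shapes and a default FWHM of 12 cm⁻¹ are conventional for
condensed-phase Raman lines. The band library has two tiers:

* a *shared* tier of strong cellular bands present in every spectrum
  (lipid C=O 1782, amide I 1655, lipid CH₂ 1449, a broad 1306–1339
  envelope, protein C–N/C–C 1128, phospholipid C–C 1097, phenylalanine
  1003, amide III 937, nucleic-acid O–P–O 782 cm⁻¹);
* *model-specific* tiers: the 3D model adds protein-associated bands at
  1662, 1448, 1336, 1246, 1002 and 851 cm⁻¹ (attributed to
  extracellular-matrix proteins), the 2D model adds 1628, 1377, 1096 and
  794 cm⁻¹.

Band amplitudes are free parameters of the generator, not measured
values. They were fixed once: the two marker bands (782 and 1655 cm⁻¹)
carry amplitude 1.0 — consistent with these being the strongest features
of the importance map and average spectrum in the experiment the package
emulates — and all other bands carry 0.3–0.7.

A measured spectrum at position $i$ is

$$x_i = \text{baseline}_i + h_i \sum_c w_c(\text{region}_i)\, s_c + \varepsilon_i$$

* $h_i$ — per-spectrum log-normal hot-spot factor with mean 1 and
  CV 0.042, anchoring the generator to the ~4.2% relative standard
  deviation of band areas measured along a uniformly enhancing wire;
* $w_c(\text{region})$ — component weights. Only the protein and
  nucleic-acid weights differ between regions (nucleus 0.5/1.0,
  cytoplasm 1.0/0.25, ECM 1.2/0.05); lipid, amino-acid and phospholipid
  weights are constant, reflecting the assumption that the
  protein-vs-nucleic-acid axis is what distinguishes subcellular regions;
* baseline — a degree-2 polynomial with coefficients drawn uniformly
  from [0, 0.1] per spectrum, a mild stand-in for fluorescence
  background;
* $\varepsilon_i$ — additive Gaussian noise, sd 0.05 of the unit peak
  amplitude (a signal-to-noise ratio around 20 for the marker bands).

The default layout alternates cytoplasm and nucleus segments flanked by
ECM, mimicking a wire threading two cells. For the labeled model pair,
both classes share the common tier at unit weights and add their specific
tier; the 3D class is additionally attenuated by a factor 0.9 because
spheroids transmit less light than a monolayer.

**What the generator does *not* emulate** — and hence what a green test
does not establish: cosmic-ray artefacts, wavenumber miscalibration,
correlated (pink) noise, cell-to-cell compositional heterogeneity within
one region type, and the saturating, strongly distance-dependent nature
of real hot-spot enhancement. Green pipeline tests demonstrate that the
algorithms recover the structure the generator plants at realistic noise
levels, not that they would survive every artefact of real instrument
data.

## Stage 1: PCA, ellipses, quadrant rule, KNN

`fit_pca()` mean-centres the intensity matrix and takes the SVD
(equivalent to the eigen-decomposition of the covariance matrix);
explained proportions are eigenvalues over total variance. Signs of
loading vectors are made deterministic by flipping each so its
largest-magnitude entry is positive.

Because the quadrant rule ("2D-characteristic bands have PC1 > 0 and
PC2 < 0; 3D-characteristic bands the converse") is stated relative to a
particular orientation of the score plot, the discrimination pipeline
re-orients PC1/PC2 by the class means — 2D mean in quadrant 4, 3D mean in
quadrant 2 — via `orient_pca_to_labels()` before applying
`key_bands_from_loadings()`. This was a genuinely open design point: a
label-free sign convention leaves the rule's class assignment arbitrary,
and re-orienting by class means is the only choice that makes the rule's
output reproducible. "High-level" loadings default to ≥ 0.5 of the
per-component maximum absolute loading; the threshold is a config knob
because no quantitative definition exists.

A practical caveat found while validating on synthetic pairs: PCA places
the entire between-class axis into a single component whenever the
within-class covariance is isotropic around it, in which case one class's
key bands fall into quadrants 1/3 and are (correctly) reported
unassigned. The package therefore guarantees *no cross-assignment* rather
than full two-sided recovery on arbitrary data; full recovery is
demonstrated on data whose latent structure actually spans both
components (see `tests/testthat/helper-fixtures.R`).

The 95% confidence ellipse uses the sample mean and covariance with
semi-axes $\sqrt{\lambda_i\,\chi^2_{0.95}(2)}$. Overlap of two ellipses
is decided by sampling 720 boundary points of each and testing
containment in the other (Mahalanobis form, margin 1e-9), plus mutual
centre containment for the nested case.

The KNN validation score uses the RMS distance on the PC1/PC2 score
pair — read as "the proportions of each spectrum in PC1 and PC2", i.e.
its score coordinates, since the per-component explained proportions are
dataset-level constants — with K = 11 and a seeded, stratified 80/20
split. Vote ties (impossible for two classes at odd K, possible in edge
cases) break to the nearest neighbour's label, then lexicographically.

## Stage 2: silhouette, forest importance, two-band re-clustering

`kmeans_pp()` implements ++ seeding (new centres drawn with probability
proportional to squared distance from the chosen set) followed by Lloyd
iterations; 10 restarts, centre-shift tolerance 1e-6, at most 300
iterations, best restart by within-cluster sum of squares. Empty clusters
are re-seeded at the farthest point. The silhouette coefficient follows
the standard per-sample form; samples in singleton clusters contribute 0,
and k = 1 is excluded from the silhouette search (the criterion is
undefined there), so a requested range starting at 1 is evaluated from 2
and noted in the result.

The random forest (compiled in `src/rf.cpp`) grows 500 bootstrap CART
trees to purity with √p candidate features per split and accumulates
mean-decrease-in-impurity importances, normalised to sum 1. 500 trees,
unlimited depth and √p mtry are the conventional classification defaults;
they are echoed into the result object. The forest is trained once on the
K-means++ labels of the full spectra (no iteration), following the
single-pass reading of the procedure.

The importance curve is smoothed by a centred 15 cm⁻¹ boxcar whose window
shrinks at the grid edges: a constant profile passes through unchanged
and an interior spike keeps its total mass exactly; mass conservation is
only approximate within half a window of the edges (the two requirements
are incompatible there, and edge bands play no role in this analysis).
`top_bands()` then reports the highest plateau-aware local maxima with a
pairwise separation of at least 50 cm⁻¹, so the two shoulders of one band
are never reported twice.

Band features are integrated areas over ±5 cm⁻¹ (areas are robust to
one-bin jitter, unlike single-point intensities), standardised per band
before the final k = 2 clustering because the two bands have unrelated
absolute scales. The cluster whose centre is higher on the band nearer
the amide I marker (1655 cm⁻¹) is labelled protein-rich. The normalised
intensity of a spectrum is $1 - d_i/\max d$ within its cluster: the
spectrum at the centre — the most representative member — scores 1. The
opposite convention ("far = strong") is defensible and available via
`intensity_direction = "far_strong"`; near-centre-strong is the default
because the centre is the best exemplar of the category.

For scoring against generator truth, nucleus maps to nucleic-acid-rich
and both cytoplasm and ECM map to protein-rich (the ECM is protein-rich
material by definition).

## Numerical choices and degenerate inputs

* CSV I/O uses one dialect (comma, "." decimal, UTF-8, mandatory header,
  17-significant-digit numerals) so round trips are lossless.
* JCAMP-DX blocks with differing abscissas are interpolated onto a common
  grid spanning the *overlap* of their ranges (a union range would
  require extrapolation, which the resampler refuses by contract).
* Cropping uses closed intervals on both ends; the 717–1827 cm⁻¹ window
  over the default grid keeps exactly 1015 features.
* Constant matrices are rejected by PCA; degenerate (constant) band
  features are rejected by the final clustering; scans of fewer than 10
  spectra are refused by the mapping pipeline; coincident points in a
  silhouette evaluation contribute 0.
* All randomness flows from explicit integer seeds; identical
  configuration gives bit-identical results, including across the
  compiled forest (a fixed per-tree Mersenne Twister stream).

## Known limitations

* Measured constants of the emulated experiment (enhancement factor
  2.53×10⁵, hot-spot RSD 4.22%, field silhouette 0.1838) depend on
  undeposited instrument data; the package reproduces the formulas and
  the qualitative claims (score 1, k = 2, SC > 0), not those numbers.
* The quadrant rule recovers both classes' bands only when the score
  geometry genuinely spans two components (see above).
* The 3D mapping path reuses the 2D machinery unchanged; no
  depth-specific tuning is attempted.
* Mean-decrease-in-impurity importance is known to spread across
  correlated neighbouring wavenumbers; the smoothing step exploits this
  rather than fighting it, but permutation importance is out of scope.
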