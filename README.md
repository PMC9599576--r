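# wirespec

Chemometric analysis of surface-enhanced Raman scattering (SERS) spectra
collected at 1 µm steps along a single silver-nanowire probe inserted into
cell-culture models. A long, thin (~300 nm) SERS-active nanowire threaded
through a cell monolayer ("2D model") or a multicellular tumour spheroid
("3D model") acts as an endoscope: every position along the wire yields a
fingerprint spectrum of the local biomolecular environment (nucleus,
cytoplasm, extracellular matrix). `wirespec` implements the two analysis
stages such an experiment needs, together with a synthetic line-scan
generator that provides ground truth for testing the whole pipeline.

## What it computes

**Stage 1 — culture-model discrimination.** Spectra from both models
(717–1827 cm⁻¹, 1015 features) are mean-centred and decomposed by PCA
(eigenvectors of the covariance matrix give loadings over wavenumbers,
eigenvalues their explained proportions). Each model's PC1/PC2 score cloud
is summarised by a 95% confidence ellipse (semi-axes √(λᵢ·χ²₀.₉₅(2)));
non-overlapping ellipses indicate separable models. Key discriminating
bands follow a quadrant rule on the loadings: bands with PC1 > 0, PC2 < 0
characterise the 2D model, bands with PC1 < 0, PC2 > 0 the 3D model. The
separation is validated by a K-nearest-neighbour classifier (K = 11) on
the score coordinates with the RMS distance

d(p, q) = √[((p₁−q₁)² + (p₂−q₂)²)/2]

under a stratified 80/20 split; the score is the fraction of correctly
classified test spectra.

**Stage 2 — molecular region mapping along the wire.** Unlabeled scan
spectra are clustered by K-means++ with the cluster count chosen by the
silhouette coefficient

SC = (1/N) Σᵢ (bᵢ − aᵢ)/max(aᵢ, bᵢ)

over k = 2…5. A random forest (500 bootstrap CART trees, Gini importance,
√p features per split — compiled, in `src/`) learns the cluster labels and
ranks every wavenumber's importance; the two top separated peaks of the
smoothed importance curve (in practice the nucleic-acid O–P–O band near
782 cm⁻¹ and the protein amide I band near 1655 cm⁻¹) are re-extracted as
integrated band areas and re-clustered at k = 2, labelling every
micrometre position *protein-rich* or *nucleic-acid-rich* with a
normalised intensity 1 − dᵢ/max(d) (1 at the cluster centre).

Also included: band-area, relative-standard-deviation and SERS
enhancement-factor formulas (EF = (I_SERS/c_SERS)/(I_ref/c_ref)), CSV and
JCAMP-DX spectral I/O, and a CLI.

## Worked example

```r
library(wirespec)

# labeled synthetic pair: 270 monolayer + 200 spheroid spectra
pair <- simulate_model_pair(generator_config(seed = 1),
                            n_2d = 270, n_3d = 200)
run_discrimination(pipeline_config(seed = 1), pair$set_2d, pair$set_3d)
#> <discrimination_report>
#>   explained: 54.2%, 14.8%
#>   ellipses overlap: FALSE
#>   KNN score: 1.0000 (k = 11, 94 test spectra)
#>   key bands: 2D: 788, ..., 794, ..., 1096, ..., 1377, ..., 1628, ... | 3D:

# unlabeled line scan along one wire, mapped to molecular regions
scan <- simulate_line_scan(generator_config(seed = 1))
map <- run_region_mapping(pipeline_config(seed = 1, n_trees = 150), scan)
map
#> <region_map>
#>   selected k: 2
#>   bands: protein 1654.0 cm^-1, nucleic acid 782.7 cm^-1
#>   silhouette of two-band clustering: 0.8459
#>   calls: nucleic_acid_rich=16, protein_rich=40
score_against_truth(map)
#> <truth_score> accuracy 1.000 on 56 positions
```

Reading the output: the two 95% ellipses do not overlap and every held-out
spectrum is classified correctly (score 1), so the two culture models are
separable in PC1/PC2 score space; the quadrant rule flags the planted
2D-characteristic bands (794, 1096, 1377, 1628 cm⁻¹). On the line scan the
silhouette selects 2 clusters, the forest's most important wavenumbers sit
at the grid points nearest 782 and 1655 cm⁻¹, and the resulting
protein/nucleic-acid calls reproduce the generator's nucleus/cytoplasm/ECM
layout exactly.

## Command line

```sh
Rscript inst/cli/wirespec simulate    --seed 1 --out out/
Rscript inst/cli/wirespec map-regions --input out/scan.csv --out out/
Rscript inst/cli/wirespec discriminate --in2d a.csv --in3d b.csv --out out/
Rscript inst/cli/wirespec metrics --input out/scan.csv \
        --center 1655 --halfwidth 6 --out out/
```

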