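# keyhabitat

Identify *key habitats* — areas that a threatened species probably occupied
historically **and** that still hold suitable vegetation today — and turn
the comparison of the two into an IUCN criterion-A2 threat assessment.

The package was built around the situation of a critically endangered
Neotropical finch whose range has been eroded by both trapping and land
transformation: historical presence records exist, confirmed absences do
not, and ground observations of habitat quality are contaminated by recent
anthropogenic change. It implements the full analysis pipeline for that
class of problem, plus a synthetic-landscape generator so every stage can
be exercised and tested without any external raster, satellite archive or
species database.

## What it computes

1. **Study area** (`delineate_study_area`): environmental layers
   (elevation, tree cover, aridity index) are resampled to a common grid
   by nearest-neighbour centers, binarized by closed suitability intervals
   (defaults 200–1500 m, 10–100 %, 2000–6500), and intersected.

2. **Historic occurrence probability** Ψ_H (`fit_maxlike`): a
   presence-only species distribution model fitted by maximum likelihood,

   ℓ(β) = Σᵢ log ψ(xᵢ; β) − n·log( |L|⁻¹ Σ_{z∈L} ψ(z; β) ),
   ψ = logistic(β₀ + βᵀx),

   over the study-area cells L. Records are split 75/25 into calibration
   and validation sets five times (`partition_records`); candidate
   covariate sets are ranked by convergence and AICc across replicates
   (`select_best_model`); replicates are evaluated against pseudo-absences
   by AUC, point-biserial correlation, max-kappa and maxSSS
   (`evaluate_fit`), and the occurrence threshold T_ΨH is the mean of the
   best replicates' kappa-argmax statistics (`select_threshold`).

3. **Vegetation degradation** (`detect_changepoint`): each location's
   16-day EVI series is quality-filtered (best QA rank per composite date,
   `filter_by_qa`), then scanned for the single most likely change point
   in mean *and* variance under a two-segment Gaussian likelihood, with an
   MBIC-style significance penalty. Post-change observations yield the
   23-value EVI phenology (`phenology`); cohort-level degradation is
   summarized with a chi-square test of independence from habitat
   category (`summarize_degradation`).

4. **Current suitability** (`fit_forest`): a bagged classification-tree
   ensemble (bootstrap resampling, 5 random predictors per split; 50,000
   trees at field scale) maps phenologies to the expert's ordinal scale
   poor < acceptable < good < excellent. The out-of-bag confusion matrix
   is corrected with ordered weights (`weighted_oob`), and per-cell class
   votes collapse to a continuous suitability index in [0, 3] with
   single-step category weights (`votes_to_index`, `predict_suitability`).

5. **Key habitats and threat category** (`key_habitat_report`): cells with
   Ψ_H > T_ΨH and currently excellent (or good+excellent) suitability;
   the Ψ_H × index overlap surface; Area of Occupancy decline
   (1 − AOO_now/AOO_hist)·100 banded into IUCN A2 categories
   (≥80 % Critically Endangered, ≥50 % Endangered, ≥30 % Vulnerable).

Rasters are lightweight in-memory `GridLayer` matrices with plain-text
ESRI ASCII grid I/O; points and EVI series travel as CSV, reports as JSON.

## Worked example

```r
library(keyhabitat)
res <- run_pipeline(default_config(), out_dir = "keyhab_demo")
res$report
```

runs the whole pipeline on a synthetic 50 km × 50 km landscape (1 km
coarse grid, 250 m fine grid, 88 presence records, 191 ground-truth
locations, 300 trees) in about ten seconds and prints, for the default
seed:

```
[occurrence] selected: TREE + AI
[occurrence] t_psi = 0.090 (replicates 5,3,2)
[evi] 83% of locations degraded
[classify] OOB error raw 12.6%, weighted 4.2%
<KeyHabitatReport: t_psi 0.090>
  historic (psi > t): 800 km2
  key habitat (excellent): 151 km2 -> decline 81.1% (Critically Endangered)
  expanded (good+excellent): 430 km2 -> decline 46.3% (Vulnerable)
```

Reading it: model selection kept the tree-cover + aridity formula (the
richer formulas fail to converge); 83 % of the simulated locations show a
significant EVI reduction (the generator degrades 85 % of them; the
change-point test misses a few); the ordered-weight correction drops the
OOB error from 12.6 % to 4.2 % because most confusions are between
adjacent categories; and of 800 km² of historically suitable area only
151 km² remains excellent today — an 81 % AOO decline, in the Critically
Endangered band (or Vulnerable under the expanded good+excellent
definition).

The same stages can be driven from the command line:

```sh
Rscript inst/cli/keyhabitat.R run --config cfg.yaml --out out/ --seed 1
Rscript inst/cli/keyhabitat.R simulate --out synth/ --seed 1
```

## Vignette

`vignettes/methods.Rmd` documents the statistical model, the synthetic
world's assumptions, all tunable parameters with their defaults, and the
numerical design choices (tie-breaks, penalties, convergence criteria,
degenerate inputs).
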