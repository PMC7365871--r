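# fnirsCCA

Cross-participant classification of second-language proficiency from fNIRS
brain-activation patterns, for researchers analysing (or prototyping
analyses of) block-design functional near-infrared spectroscopy studies.
The package implements the complete chain — synthetic cohort generation,
block-design preprocessing, a per-channel activation statistic, sparse-CCA
stability selection, and leave-one-out classification — as tested,
reusable R functions organised around S4 data classes.

## The method

A cohort of participants (high vs low L2 proficiency, balanced) listens to
questions in three languages (L1 native, L2 second, L3 unknown) in a block
design: two runs × 15 trials, five per language, 18-s question periods,
44 measurement channels at 10 Hz from two 3×5 optode grids.

Per channel and participant, oxy- and deoxy-hemoglobin block amplitudes
(5–18 s window averages of band-passed, baseline-corrected 33-s epochs)
are contrasted with a Welch-style activation indicator

$$a = \frac{\overline{oxy} - \overline{deoxy}}
           {\sqrt{S^2_{oxy}/n + S^2_{deoxy}/m}},$$

giving a 44-dimensional activation vector A = (a₁, …, a₄₄) per participant
and language. Informative channels are found by L1-penalised sparse
canonical correlation analysis between the L2 feature matrix X and the
label Y,

$$\max_{v_X, v_Y} v_X^\top X^\top Y v_Y
  \quad \text{s.t.} \quad \|v_X\|_1 \le \lambda_X,\ \|v_Y\|_1 \le \lambda_Y,\
  \|v_X\|_2 \le 1,\ \|v_Y\|_2 \le 1,$$

refit in every leave-one-out fold; channels selected in more than
⌊0.95 N⌋ folds (38 of 40, or 36 of 38) are the *common informative
features*. Proficiency is then classified — linear SVM, sparse logistic
regression with automatic relevance determination, and KNN (K = 5) — under
leave-one-out cross-validation, on all 44 channels and on the selected
subset, with accuracy (TP+TN)/(TP+TN+FP+FN).

Because the study's recordings are available only on request, the package
ships a synthetic cohort generator (double-gamma HRF, individual
differences, physiological + white noise, group-dependent L2 amplitudes on
configurable informative channels) that reproduces the paradigm's
statistical structure; see the methods vignette
(`vignettes/fnirsCCA-methods.Rmd`) for the model and every default.

## A worked example

```r
library(fnirsCCA)

cfg <- simulationConfig(nPerGroup = 5, effectSize = 4,
                        informativeChannels = c(1, 16), seed = 71)
report <- runFullPipeline(cfg, targetSupport = 3)
report
#> PipelineReport (seed 71): 10 participants retained, features 1, 16
#>  language classifier featureSet nFeatures accuracy TP TN FP FN
#>        L1        svm      all44        44      0.5  3  2  3  2
#>  ...
#>        L2        svm      all44        44      1.0  5  5  0  0
#>        L2        svm   selected         2      1.0  5  5  0  0
#>        L2        slr   selected         2      0.7  4  3  2  1
#>        L2        knn   selected         2      0.8  3  5  0  2
#>  ...
#>        L3        svm   selected         2      0.6  3  3  2  2
```

The stability selection recovered exactly the two channels the simulation
planted (counts 10/10 across the folds, threshold ⌊0.95·10⌋ = 9), the L2
classification separates the groups well above the 0.5 chance level, and
the native (L1) and unknown (L3) languages — which carry no
group-dependent signal — sit near chance. Selected channels are annotated
with the packaged anatomical lookup:

```r
report$annotation
#>   channel hemisphere mni_x mni_y mni_z                               anatomy
#> 1       1       Left   -50    22    38     Left middle frontal gyrus (BA 44)
#> 2      16      Right    71   -25     4 Right superior temporal gyrus (BA 21)
```

`runFullPipeline(..., outputDir = "run1")` additionally writes
`manifest.json`, `features_{L1,L2,L3}.csv`, `selection_profile.csv`,
`results.json` and `report.md`. A thin command-line wrapper with
`run-all` / `simulate` / `annotate` subcommands lives at
`inst/scripts/fnirs-pipeline.R`.

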