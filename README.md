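# cortexmap

Quantification pipelines for sensory-evoked cortical imaging and perisomatic
inhibitory staining, with synthetic ground-truth generators for end-to-end
validation.

The package implements three measurement workflows from mouse somatosensory
cortex experiments:

* **Widefield fluorescence (%ΔF/F) mapping** — trial quality control (≥ 10 %
  frame-deviation artifact rejection), trial averaging, 1-px Gaussian
  smoothing, %ΔF/F normalization against the pre-stimulus baseline, evoked
  response-window detection, half-maximum cortical-map segmentation with area
  measurement, temporal-phase durations (onset, time-to-peak, attack, decay,
  total) and the adjacent negative "surround" signal.
* **Perisomatic PV⁺ density** — disk median filtering, grouped (5→1) maximum
  projection, Bernsen local adaptive thresholding, a watershed-closed control
  image, seeded 4-connected region growing with disk dilation, and stained
  area normalized by soma cross-section and slice count.
* **Behavior / ancillary histology** — von Frey withdrawal thresholds (60 %
  criterion, 2.0 g ceiling, two-paw combination), dendritic-spine density
  with branch-class grouping, ROI integrated density, and a generic
  labeled-cell counter.

Each workflow has a paired synthetic generator (`genFAISession`,
`genConfocalPVStack`, `genVFResponses`) that produces realistic inputs with
known ground truth, so every stage is testable against an oracle.

## Quick start

```r
library(cortexmap)

# --- widefield session: generate, analyze, read the metrics ---
cfg   <- SessionConfig()                        # 5 Hz, 31 frames, stim at 6
truth <- FAIGroundTruth(centerXY = c(64L, 64L), artifactTrials = c(3L, 8L),
                        seed = 11)
sess  <- genFAISession(cfg, truth, nTrials = 10)
res   <- runFAISession(sess$trials, cfg)
res$metrics
#> FAIMetrics
#>   peak intensity: 7.008 %dF/F over 110 px map
#>   onset 0.20 s, time-to-peak 0.80 s, attack 0.60 s, decay 4.20 s, total 4.80 s (censored)
#>   surround minimum: -0.007 %dF/F
#>   trials kept/rejected: 8/2

# --- perisomatic density around one soma shadow ---
gt <- PVGroundTruth(somaCenters = c(45L, 45L), nSlices = 5L, seed = 33)
pv <- genConfocalPVStack(gt, shape = c(90, 90))
cs <- preprocessStack(pv$stack, group = 5, selected = 1)
batchQuantify(cs, rbind(c(45L, 45L)))$meanDensity
#> [1] 0.2868633

# --- von Frey threshold ---
g <- genVFResponses(VFGroundTruth(trueThresholdG = 0.4, slope = Inf, seed = 4))
vonFreySession(g$ladderG, g$responses)@combinedG
#> [1] 0.4
```

(Exact numbers above are reproducible: all generators are seeded.)

## Command-line interface

A thin CLI wraps the same functions for file-based runs:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cortexmap.R", package="cortexmap"))') \
    fai analyze --session session.yaml --trials trials/ --out results/
```

Subcommands: `synth fai|confocal|vf`, `fai analyze`, `pv quantify`,
`vf threshold`, `spines density`, `roi intden`. Every run writes a
`manifest.json` (tool version, seed, parameter echo, input MD5 digests);
reruns with identical inputs reproduce byte-identical CSV outputs.

## Validation

* Unit and property tests (testthat): operators are checked against
  exhaustive brute-force oracles (per-pixel Bernsen, BFS flood fill, direct
  convolution, …) and the pipelines against generator ground truth —
  including an acceptance suite in `tests/testthat/test-acceptance.R`:

  ```r
  testthat::test_dir("tests/testthat", package = "cortexmap",
                     load_package = "installed")
  ```

* A standalone acceptance run against the installed package writes the main
  computed quantities (parameter-recovery errors, rejection accuracy,
  density-vs-truth comparisons, psychometric recovery) as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

See the methods vignette (`vignettes/cortexmap-methods.Rmd`) for the
measurement models, parameter defaults, and numerical conventions (all
indices are 1-based; reflective image borders; Euclidean disk structuring
elements).
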