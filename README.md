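# discT2

Quantitative T2 relaxometry of the lumbar intervertebral disc (IVD) from
multi-echo sagittal MRI, with the complete test-retest reliability suite
needed to use disc T2 as a longitudinal outcome measure.

Disc T2 reflects tissue hydration: the nucleus pulposus of a healthy adult
lumbar disc relaxes slowly (T2 ~ 120-150 ms), the annulus fibrosus quickly
(~ 80-100 ms). To decide whether an individual's change over time is real
rather than measurement error, one needs the measurement chain *and* its
error statistics. `discT2` provides both, plus a synthetic multi-echo spine
phantom with full ground truth so the whole chain can be validated end to
end without access to clinical images.

## What is inside

* **Phantom** (`phantomSpec`, `renderEchoStack`,
  `generateLongitudinalDataset`): sagittal spine stacks — vertebral bodies,
  dark endplates, tilted lens-shaped discs with five-subregion T2 ground
  truth — rendered as S0 e^(-TE/T2) over 16 echo times (10.9 ... 174.4 ms)
  with Rician noise, and longitudinal subject x session datasets with known
  variance components (true T2 = mu + b_i + w_ij).
* **Segmentation** (`segmentDiscs` and the individual operations):
  semi-automated disc delineation — 1 x 15 vertical median filter, spine
  centre by the 100-unit difference rule, endplate seeds as sub-150-unit
  local minima, 3-of-8-neighbour contour tracking, minimum-cost graph
  search (Dijkstra) through support points, slice-to-slice support-point
  propagation, 80-unit anterior/posterior border rule, mask extraction.
* **Subregions** (`partitionDisc`, `regionMeanSignals`): image-moment
  ellipse orientation, rotation to the horizontal, five equidistant-width
  anterior-to-posterior bands, signal extraction in the original frame.
* **T2 fitting** (`fitMonoexponential`, `wholeDiscT2`, `nuclearT2`,
  `subregionT2Averaged`): mono-exponential least squares on the region-mean
  decay (log-linear start, Levenberg-Marquardt refinement, T2 in
  [1, 2000] ms).
* **Reliability** (`icc11`, `semFromSdIcc`, `minimumDetectableDifference`,
  `mdPercent`, `coefficientOfVariation`, `blandAltman`, `fdrAdjust`,
  `sessionCorrelationTable`, `reliabilityTable`): one-way random-effects
  ICC(1,1) with exact F-based CIs, SEM = SD * sqrt(1 - ICC),
  MD = SEM * sqrt(2) * 1.96, MD%, within-subject CV with chi-square CI,
  Bland-Altman limits of agreement with linear-bias regression and
  Benjamini-Hochberg control, between-session Pearson correlations, and
  degeneration-grade-stratified tables.
* **Pipeline** (`runConfig`, `runPipeline`): phantom (or supplied stacks)
  to report bundle — records CSV, reliability tables, Bland-Altman
  results, correlation matrix, QC overlay, run manifest — deterministic
  given a seed. A thin command-line front end ships in
  `inst/cli/disct2.R` (verbs `simulate`, `segment`, `fit-t2`,
  `reliability`, `run-all`).

## Worked example

Simulate a 12-subject, nine-session longitudinal study (with the attrition
pattern 12, 12, 12, 12, 11, 10, 10, 8, 8), segment every stack, fit T2 and
tabulate reliability:

```r
library(discT2)
cfg <- runConfig(phantom = phantomSpec(), study = studySpec(),
                 measures = c("whole", "nuclear"), seed = 1L)
run <- runPipeline(cfg)
run$table[, c("measure", "globalMean", "icc", "sem", "md", "mdPct", "cv",
              "classification")]
```

```
         measure globalMean   icc  sem   md mdPct   cv classification
1     whole L1/2        109 0.975 1.72 4.78  4.38 1.68      excellent
2     whole L2/3        109 0.975 1.71 4.75  4.37 1.68      excellent
3     whole L3/4        108 0.975 1.72 4.78  4.41 1.69      excellent
4     whole L4/5        109 0.975 1.73 4.79  4.39 1.69      excellent
5    whole L5/S1        111 0.975 1.71 4.73  4.27 1.65      excellent
6     whole AvLx        109 0.975 1.71 4.75  4.35 1.67      excellent
7   nuclear L1/2        131 0.943 2.30 6.38  4.86 1.83      excellent
8   nuclear L2/3        131 0.925 2.56 7.09  5.42 2.14      excellent
9   nuclear L3/4        131 0.933 2.40 6.66  5.08 1.90      excellent
10  nuclear L4/5        131 0.939 2.34 6.48  4.95 1.84      excellent
11 nuclear L5/S1        131 0.939 2.32 6.44  4.90 1.89      excellent
12  nuclear AvLx        131 0.966 1.71 4.73  3.61 1.38      excellent
```

Reading the output: `globalMean` (ms) pools all observations of the
measure; `icc` is the one-way ICC(1,1), here ~ 0.975 for whole-disc T2 —
the phantom defaults encode a true ICC of 0.98 (between-subject SD
13.3 ms, within-subject SD 1.9 ms). `sem` (ms) is the measurement error
on a single observation, `md` (ms) the smallest individual change
distinguishable from that error at 95% confidence (here ~ 4.8 ms, i.e.
`mdPct` ~ 4.4% of the mean), and `cv` the within-subject test-retest
variability (~ 1.7%, against a true 1.9/109 ~ 1.8%). Averaging levels
("AvLx") lowers the nuclear SEM and CV, as expected for exchangeable
noise. The per-level rows are near-identical because phantom discs share
their true T2 — real spines differ by level.

`run$blandAltman` holds the per-measure baseline-versus-follow-up
comparisons (limits of agreement, slope tests, FDR-adjusted p-values);
`run$correlations` the session x session Pearson matrix (whole-disc upper
triangle, nuclear lower).

## Documentation

The methods vignette (`vignettes/discT2-methods.Rmd`) documents the model
and every algorithmic rule (thresholds, tie-breaks, degenerate cases), the
phantom's calibration and its limits, and the design decisions taken where
the underlying procedure leaves choices open.
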