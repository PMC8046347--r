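---
title: "Quantitative lumbar disc T2 and its long-term reliability: methods"
author: "discT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative lumbar disc T2 and its long-term reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discT2)
```

## The problem

The T2 relaxation time of water protons in the intervertebral disc (IVD) is
a quantitative marker of disc hydration and matrix composition: the
well-hydrated nucleus pulposus relaxes slowly (T2 roughly 120--150 ms in
healthy adult lumbar discs) while the collagen-rich annulus fibrosus relaxes
quickly (roughly 80--100 ms). Before disc T2 can serve as a longitudinal
outcome measure, two things must be established: a reproducible measurement
chain from multi-echo sagittal MRI to per-region T2 values, and the
test-retest statistics (ICC, SEM, minimal detectable difference, CV,
Bland-Altman agreement) that say how large an individual change must be
before it exceeds measurement error.

`discT2` implements both halves as a tested pipeline, and -- because the raw
clinical MRI behind such studies is generally not redistributable -- couples
them to a synthetic multi-echo spine phantom with complete ground truth, so
that every stage can be validated end to end.

## The measurement chain

**Acquisition model.** A session is an `EchoStack`: six sagittal slices,
each imaged at sixteen echo times (10.9, 21.8, ..., 174.4 ms), with rows
running cephalocaudally and columns anteroposteriorly. The noise-free pixel
value at echo time $TE$ is the mono-exponential decay
$S(TE) = S_0 \exp(-TE/T_2)$ of that pixel's tissue; magnitude images carry
Rician noise.

**Semi-automated segmentation.** The delineation follows a published
semi-automated scheme driven by raw-intensity thresholds:

1. The second-echo image (highest disc-bone contrast) is median-filtered
   with a one-pixel-wide, 15-row vertical window (`verticalMedianFilter`,
   reflection padding at the borders).
2. The spine centre is the pixel column with the most pixels at least 100
   units brighter than the median image (`locateSpineCentre`; the signed
   difference is used -- a pixel must be *brighter* than its median).
   Because discs are only a handful of pixels tall, the vertical median at
   a disc pixel is dominated by the surrounding vertebral tissue, so disc
   pixels light up strongly in this difference.
3. Strict local minima of the centre-column profile below 150 units mark
   the dark vertebral endplates (`detectEndplateSeeds`; constant plateaus
   report their lower-middle row, runs touching the profile ends are
   ignored).
4. From each seed, contour tracking walks anteriorly and posteriorly,
   stepping into the adjacent column within $\pm 2$ rows wherever at least
   three of the candidate's eight neighbours are below 150 units
   (`trackEndplateContours`; among qualifying candidates the darkest pixel
   wins, ties prefer the smallest row step).
5. The anterior/posterior disc borders are found per row by scanning
   outward from the centre column for the first column where the
   across-echo averaged image and the median image differ by at least 80
   units (`findApBorders`); unresolved rows inherit the nearest resolved
   row's border, and a crossing at the centre column itself is flagged
   degenerate.
6. Disc masks are the pixels strictly between the paired endplate contours
   and strictly inside the row borders (`extractDiscMasks`); overlap
   between filled discs is treated as a contour failure and raises an
   error rather than being resolved silently.

Where an operator would mark roughly eight support points per disc and
connect them by a minimum-cost graph search, the package auto-places the
points on the tracked contours (`placeSupportPoints`) and provides the
graph search itself (`dijkstraBoundary`): the cost of entering a pixel is
$w_1 (1-\cos\theta)/2 + w_2\,\bar g$, where $\theta$ is the angle between
the pixel's gradient and the mean gradient at the two flanking support
points and $\bar g$ the grey value normalised to $[0,1]$ over the search
window. Both weights default to 0.5; gradients use central differences
after Gaussian smoothing with $\sigma = 1$ px. Support points can be
propagated to the neighbouring slice by appearance matching
(`propagateSupportPoints`). An operator's point list can be supplied as CSV
(`readSupportPoints`) in place of the automatic placement.

**Subregions.** Each disc mask is reduced to its image-moment ellipse; the
angle between the major axis and the x-axis is removed by rotation about
the centroid (`fitEllipseOrientation`, `rotateToHorizontal`), and the
rotated width is split into five contiguous bands of equal width --
anterior annulus (1) to posterior annulus (5), with remainder columns
assigned to the anterior-most bands (`partitionFive`). Band membership is
then mapped *back* onto the original, unrotated pixels by rotating their
coordinates (`partitionDisc`), so the signal entering the T2 fit is never
interpolated. Nearest-neighbour resampling keeps the rotated mask's area
within 2% of the original.

**T2 estimation.** For every region, the per-echo mean signal is extracted
once per session and fitted with $S_0 e^{-TE/T_2}$
(`regionMeanSignals`, `fitMonoexponential`): log-linear initialisation on
the positive signals, then Levenberg-Marquardt refinement with T2 bounded
to [1, 2000] ms. The fit runs on the region-mean decay, not per pixel. Two
primary measures follow the convention of the underlying protocol: *whole
IVD T2* (whole-disc fit averaged over the six slices, unweighted) and
*nuclear T2* (subregion 3 on the third -- central -- anatomical slice);
secondary measures are the per-subregion values averaged across slices.
The six rendered discs are labelled T12/L1 to L5/S1; the most cephalad disc
is retained internally but excluded from default reports, leaving the five
lumbar levels.

## The reliability suite

For a subjects $\times$ sessions series of one measure:

* **ICC(1,1)** (`icc11`): one-way random-effects ANOVA,
  $\mathrm{ICC} = (BMS - WMS)/(BMS + (k-1) WMS)$, with
  $k_0 = (N - \sum k_i^2/N)/(n-1)$ replacing $k$ under missing sessions,
  and the exact F-based 95% CI. Classification uses the conventional
  bands: poor $< 0.40$, moderate $[0.40, 0.60)$, good $[0.60, 0.75)$,
  excellent $\ge 0.75$.
* **SEM** (`semFromSdIcc`): $SD \sqrt{1 - \mathrm{ICC}}$, where $SD$ pools
  all observations of the series; negative ICC estimates are clamped to
  zero inside this formula only, with a warning.
* **MD** (`minimumDetectableDifference`): $SEM \cdot \sqrt{2} \cdot 1.96$,
  and **MD%** $= 100\,MD/\text{mean}$. SEM/MD intervals are propagated
  from the ICC interval; because published tables round the ICC bounds
  first, agreement with printed interval bounds is asserted as
  containment, not equality.
* **CV** (`coefficientOfVariation`): per subject, the SD across sessions
  over the subject mean; reported as 100 times the RMS over subjects, with
  a chi-square CI on $\sum(k_i - 1)$ degrees of freedom.
* **Bland-Altman** (`blandAltman`): each follow-up against baseline;
  limits of agreement are the mean difference $\pm 1.96$ SD of the
  differences, and linear bias is tested by regressing the difference on
  the pair mean. With the five lumbar levels plus the level average for
  both primary measures, 12 measures $\times$ 8 follow-ups give 96
  comparisons; slope p-values are Benjamini-Hochberg adjusted
  (`fdrAdjust`).
* **Between-session correlations** (`sessionCorrelationTable`):
  pairwise-complete Pearson r for every session pair, whole-disc in the
  upper triangle and nuclear in the lower.

`reliabilityTable` assembles one row per measure (per-level rows, the
averaged-levels "AvLx" row computed on per-subject level-averaged values,
and optional degeneration-grade strata in which each disc is treated as
the unit of analysis).

## The phantom: what it emulates and what it does not

`phantomSpec` renders stacked rectangular vertebral bodies separated by
tilted, lens-shaped discs, with two-pixel dark endplate lines at every
vertebra-disc interface. Defaults: 16 echoes at 10.9--174.4 ms, six slices
of identical geometry with independent noise, 0.781 mm pixels, six discs
with subregion T2 of (93, 100, 130, 106, 81) ms anterior to posterior
(nucleus high, annulus low; whole-disc near 100 ms), and per-disc tilts
from $-9^\circ$ to $+10^\circ$ increasing caudally, echoing lumbar
lordosis.

The intensity scale is the package's own calibration, not a scanner match:
the published thresholds are raw scanner units with unknown receiver
scaling, so the defaults are chosen to place each tissue where the
thresholds expect it. On the second echo, discs render at roughly 305--340
units, vertebral bodies at 175, endplates at 100 and background at 0,
which yields (i) a locate difference of 130--200 units at disc pixels,
comfortably above 100; (ii) endplate minima below 150 with bone above it;
and (iii) an averaged-minus-median difference below 80 units everywhere
inside the disc but at least 100 units at the first column outside the
disc tip. Requiring a full 150 units of disc-bone contrast, as the
brightest-contrast rule might suggest, is incompatible with (iii) for
nucleus T2 near 130 ms; the calibration therefore favours the border
rule's operating regime, which is what the segmentation actually depends
on. The default noise is Rician with $\sigma = 7$, i.e. SNR of about 50 at
the first disc echo.

A known, deliberate property: with the per-row first-crossing border rule,
image rows that cross a *tilted* endplate are truncated at the crossing,
so strongly tilted discs lose a thin wedge near the endplates (per-disc
Dice about 0.89 at $10^\circ$ tilt, near 1.0 when horizontal). This is
faithful to the delineation rule rather than a rendering artifact, and it
barely affects T2 because the lost pixels come from the same homogeneous
regions that remain.

Longitudinal datasets (`studySpec`, `generateLongitudinalDataset`) follow
a one-way random-effects model: subject $i$, session $j$ shifts every
subregion T2 by $b_i + w_{ij}$ with $b_i \sim N(0, \sigma_B^2)$ and
$w_{ij} \sim N(0, \sigma_W^2)$, so the true ICC is
$\sigma_B^2/(\sigma_B^2 + \sigma_W^2)$. Defaults
($\sigma_B = 13.3$ ms, $\sigma_W = 1.9$ ms) give a true ICC near 0.98 and
a true within-subject CV near 1.9% at the 102 ms whole-disc mean,
matching the reliability regime reported for healthy adults. The default
layout is 12 subjects over nine sessions with attrition
(12, 12, 12, 12, 11, 10, 10, 8, 8); dropped subjects leave from the end of
the roster and do not return. The subregion ground-truth labels are
generated by the same band-partition code the analysis uses, so geometric
disagreement between truth and analysis is zero by construction --
phantom-based tests therefore validate the *measurement chain*, not the
band convention itself.

What the phantom does not emulate: anatomically realistic spine shape,
partial-volume averaging at tissue interfaces, B0/B1 field inhomogeneity,
motion, or within-region T2 texture. Passing phantom tests consequently
shows that the chain recovers known signals under the stated geometry and
noise; it does not certify performance on clinical images, where operator
support-point placement and manual correction remain part of the
procedure.

## Numerical choices and degenerate inputs

* Median filtering pads by reflection, avoiding spurious signal-versus-zero
  differences at image borders.
* Spine-centre ties break to the smallest column; plateau minima report
  their lower-middle row; contour-tracking ties prefer the smallest row
  step, then the upper row.
* The graph search adds an infinitesimal per-step cost so that a
  degenerate all-equal cost field still returns the minimal 8-connected
  path; reported costs are pure node-cost sums.
* A circle (no preferred axis) reports orientation $0^\circ$ by
  convention; masks under 10 pixels refuse the ellipse fit.
* Band widths not divisible by five give their remainder columns to the
  anterior-most bands; the anterior direction is an explicit flag
  (`anteriorLeft`), never guessed from the image.
* T2 fits that fail to converge return the log-linear estimate flagged
  `converged = FALSE`; all-nonpositive decays are an error.
* Negative ICC estimates are reported as computed and clamped only inside
  the SEM formula; fewer than three complete pairs make a Bland-Altman
  comparison "insufficient" rather than an error.

## Problem sizes used by the test-suite simulations

Chosen to make the stochastic checks informative while keeping a full run
inexpensive: parameter-recovery simulations use 500 replicates of the
12-subject, 9-session layout at the value level; image-chain checks use
the full six-disc phantom (two slices for T2 recovery, one slice across 20
geometry-jitter seeds for segmentation accuracy); the end-to-end
study-emulation check runs 100 replicate studies at a reduced image scale
(one slice, two discs, 64-pixel width) with the full segmentation in the
loop. The acceptance script runs one complete 12 x 9 study at the full
default image size.

## Worked example

```{r example, eval = FALSE}
library(discT2)
cfg <- runConfig(phantom = phantomSpec(), study = studySpec(),
                 measures = c("whole", "nuclear"), seed = 1L)
run <- runPipeline(cfg)
run$table[, c("measure", "globalMean", "icc", "sem", "md", "mdPct", "cv",
              "classification")]
```

The README shows the printed output of this run and reads it against the
reliability regime the defaults encode.

## Known limitations

* ICC types other than (1,1) (e.g. two-way models) are out of scope, as is
  any mixed-model variance decomposition.
* The nucleus is geometric (central fifth, central slice), not an
  intensity-derived nucleus boundary.
* Fully operator-free segmentation of clinical images is not claimed; the
  automatic support-point placement exists for unattended testing.
* The CV confidence interval treats the squared within-subject CV as a
  pooled variance on $\sum(k_i-1)$ degrees of freedom; this is one
  reasonable convention among several in the reliability literature.
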