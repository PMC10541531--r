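# SpectASC

Does attenuation and scatter correction (ASC) change the clinical answer of
a dopamine transporter (DAT) SPECT scan?  In routine use, DAT-SPECT with
^123^I-FP-CIT is read as a binary decision — *normal* versus
*Parkinson-typical reduced* striatal uptake — either visually or by a
semi-quantitative putamen specific binding ratio (SBR).  Photon attenuation
and scatter distort the reconstructed activity severely (the striatal signal
loses on the order of 70% to attenuation alone), so ASC is mandatory for
quantitative research use; whether it matters for the binary clinical
categorization is a separate question, because both the visual read and the
SBR are contrast-based measures in which attenuation and scatter partly
cancel.

`SpectASC` is an R package for studying exactly this question in a fully
controlled setting.  It provides, as Bioconductor-style S4 components:

* a **striatal digital phantom generator** — ellipsoidal brain with
  embedded caudate/putamen structures of configurable specific binding, a
  uniform-attenuation forward model, broad-Gaussian scatter contamination,
  7 mm FWHM resolution blur and Poisson count noise; cohorts are two-class
  mixtures (normal / reduced) with hemispheric asymmetry and known ground
  truth;
* **automatic head-contour delineation** (25 mm FWHM smoothing, per-slice
  ellipse fit to the 30% iso-contour, with edge-localization refinement)
  and **first-order Chang uniform attenuation correction** with the
  narrow-beam coefficient mu = 0.146/cm;
* **DVR intensity scaling** by the 75th percentile of a nonspecific
  reference region;
* **hottest-voxel putamen SBR**: mean of the hottest 10 ml inside an
  oversized unilateral putamen mask, minus 1, summarized by the minimum
  over hemispheres;
* **two-Gaussian histogram calibration**: the SBR histogram (bin width 0.1)
  is fitted by

      A1*exp(-(x-M1)^2/(2*SD1^2)) + A2*exp(-(x-M2)^2/(2*SD2^2)),

  giving the effect size `d = (M2-M1)/sqrt((SD1^2+SD2^2)/2)` and the
  normal/reduced cutoff `c = (SD2*M1 + SD1*M2)/(SD1+SD2)`;
* **agreement and power statistics**: 2x2 cross tables, Cohen's kappa with
  asymptotic standard error, discrepancy percentages, k x 2 chi-square
  homogeneity tests, and the exact unconditional power of the one-sided
  McNemar test.

The package ships the published reference tables of a large clinical
evaluation (n = 1740 scans reconstructed both without and with ASC) under
`inst/extdata/`, and its test suite checks the statistical machinery against
those published values.

## Worked example

Simulate a 200-scan cohort with the default forward model, measure both
arms, calibrate each arm's cutoff independently, and compare the binary
categorizations:

```r
library(SpectASC)
cohort <- CohortSpec(nScans = 200, seed = 42)
res <- runExperiment(cohort)
res$fits$asc
#> Two-Gaussian histogram fit
#>   reduced: A1 = 25.924, M1 = 0.497, SD1 = 0.126
#>   normal:  A2 = 16.159, M2 = 1.378, SD2 = 0.286
#>   effect size d = 3.986, cutoff c = 0.767, SSE = 150.3 (n = 200)
res$fits$no_asc
#> Two-Gaussian histogram fit
#>   reduced: A1 = 40.234, M1 = 0.276, SD1 = 0.076
#>   normal:  A2 = 21.581, M2 = 0.900, SD2 = 0.223
#>   effect size d = 3.741, cutoff c = 0.435, SSE = 94.51 (n = 200)
res$crossTable
#>           normal reduced
#>   normal     116       4
#>   reduced      0      80
sprintf("kappa = %.3f, discrepant = %.2f%%", res$kappa$kappa, res$discrepancyPct)
#> "kappa = 0.959, discrepant = 2.00%"
```

Reading the output: without ASC the measured SBR scale is compressed
(normal-class mean 0.90 versus 1.38 with ASC) — attenuation and scatter
suppress striatal contrast — yet the *separation* between the normal and
reduced populations is nearly unchanged (effect size d = 3.74 versus 3.99),
and the two independently calibrated arms classify 98% of scans
identically (kappa 0.96).  That is the mechanism by which ASC can matter
greatly for quantification while barely affecting the binary clinical
categorization.

The post-hoc power of the paired comparison is available directly:

```r
mcnemarPower(n = 1740, pDiscordant = 0.05, oddsRatio = 2)
#> 91.9  (percent; exact unconditional, one-sided 5% level)
```

## Package layout

* `R/` — S4 classes (`SpectVolume`, `PhantomSpec`, `BodyContour`,
  `ScanPair`, `TwoGaussianFit`, ...) and the module implementations
  (phantom, attenuation, preprocessing, SBR, mixture, agreement, pipeline).
* `vignettes/spectasc-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical details, limitations.
* `inst/extdata/` — published reference tables (see `?referenceTable`).
* `tests/testthat/` — unit, property and acceptance tests.
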