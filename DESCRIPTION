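Package: SpectASC
Title: Attenuation and Scatter Correction Effects on Semi-Quantitative
    Dopamine Transporter SPECT
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for studying the impact of
    uniform attenuation and scatter correction (ASC) on the semi-quantitative
    analysis of dopamine transporter (DAT) SPECT. Provides a striatal digital
    phantom generator with Poisson count noise, automatic head-contour
    delineation with first-order Chang uniform attenuation correction,
    distribution-volume-ratio intensity scaling, hottest-voxel putamen
    specific binding ratio (SBR) quantification, two-Gaussian histogram
    calibration of the normal/reduced cutoff, and agreement statistics
    (Cohen's kappa, discrepancy proportions, chi-square homogeneity, exact
    McNemar power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Spatial, Preprocessing, StatisticalMethod
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agreement.R'
    'volume.R'
    'attenuation.R'
    'mixture.R'
    'phantom.R'
    'sbr.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
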