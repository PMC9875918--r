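Package: prepair
Title: Unsupervised Physiological Noise Correction of fMRI from Phase and
    Magnitude EPI Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies respiratory and cardiac noise waveforms directly from
    echo-planar imaging (EPI) time series, using both the magnitude and the
    phase of the complex MR signal, without external physiological recordings.
    Slice-averaged signals are detrended and reordered by slice acquisition
    time to obtain a time series sampled at the slice repetition interval, so
    cardiac fluctuations are critically sampled even at long volume TRs.
    Fundamental frequencies are located by an iterative spectral search that
    zeroes sidebands of the slice-reordering carrier (k/TR +/- f) and the
    cold-head pump line, the better source (magnitude or phase) is selected
    per noise type by a variance-improvement test, and two-harmonic Fourier
    regressors of the cardiac and respiratory cycle phase are built per slice
    and removed from the magnitude images by voxelwise regression. Includes a
    synthetic EPI generator with known ground truth and an evaluation battery
    (lag-aware correlation with external recordings, sliding-window
    spectrograms, band-power removal proportions, out-of-band power
    fluctuation, temporal SNR gain).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
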