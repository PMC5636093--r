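Package: scesmap
Title: Activation Detection and Mapping of Epidurally Evoked Potentials in
    Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for stimulus-triggered analysis of surface electromyography
    recorded during epidural spinal cord stimulation (scES) mapping
    experiments. Epochs multi-channel EMG into a stimulus-locked segment
    matrix, denoises the matrix as a 2-D image with a generalized Gaussian
    Markov random field smoother, detects evoked potentials with an
    approximated generalized likelihood-ratio (CUSUM) detector or a
    Teager-Kaiser energy comparator, estimates per-muscle recruitment
    threshold voltages, extracts response features (peak-to-peak amplitude,
    latency, integrated EMG), and renders recruitment colormap images.
    Includes a seeded EMG simulator with known ground truth and an SNR-sweep
    benchmark harness for comparing detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
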