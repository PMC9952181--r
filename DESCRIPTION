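Package: vbdtw
Title: Voting-Based Dynamic Time Warping for Wearable-Sensor Classroom
    Behavior Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for perceiving and identifying classroom behaviors
    from wearable inertial sensors (3-axis accelerometer + 3-axis gyroscope).
    Implements Voting-Based Dynamic Time Warping (VB-DTW) valid-segment
    extraction from fixed-length motion recordings, window-slicing data
    augmentation with test-time majority voting, four neural-network
    classifier families (DNN, LSTM, BiLSTM, 1-D CNN) behind one training
    contract, Jaccard and accuracy evaluation with ablation harnesses, and a
    synthetic multi-participant dataset simulator with ground-truth segment
    indices so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
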