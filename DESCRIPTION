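Package: equispeed
Title: Horse Speed Estimation from Body-Mounted IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating horse locomotion
    speed from seven body-mounted inertial measurement units (IMUs). Generates
    synthetic multi-gait accelerometer/gyroscope recordings with known
    ground-truth speed, low-pass filters the signals and cuts speed-synchronized
    256-sample windows, extracts 23 time- and frequency-domain features per
    channel (138 per IMU location), performs sequential floating forward
    selection (SFFS) with an RMSE improvement criterion, trains five regressor
    families (SVM, decision tree, random forest, boosted trees, Gaussian
    process regression) under leave-one-subject-out cross-validation, reports
    MAE/RMSE/nRMSE overall and per gait, and fits the stride-frequency
    polynomial baseline for comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    zoo,
    jsonlite,
    ranger,
    rpart,
    e1071,
    kernlab,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
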