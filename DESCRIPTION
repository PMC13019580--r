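Package: pedvol
Title: Interpretable Basis-Decomposition Forecasting of Pediatric Patient Volumes
Version: 0.1.0
Authors@R: person("pedvol", "maintainers", email = "pedvol@example.org", role = c("aut", "cre"))
Description: Multivariate daily patient-volume forecasting with an interpretable
    recurrent basis-expansion network: LSTM-backed trend (polynomial basis),
    seasonal (Fourier basis) and residual blocks chained by dual-residual
    stacking and fused through a three-head feature-channel attention layer.
    Includes panel CSV ingestion, min-max scaling, chronological splitting and
    sliding-window construction; rolling and recursive multi-step prediction;
    RMSE/MASE/Pearson evaluation with Diebold-Mariano comparison, lag and
    peak-error quantification, and two-level moving-block bootstrap confidence
    intervals; regime-adaptive split-conformal prediction intervals; and a
    seeded generator of EHR-like synthetic count panels with known trend,
    seasonal, changepoint and overdispersed-noise structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
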