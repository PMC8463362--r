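Package: thromboperv
Title: Thrombus Perviousness Measurement from Paired NCCT/CTA Imaging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures thrombus perviousness in large-vessel-occlusion stroke
    imaging from paired non-contrast CT (NCCT) and CT angiography (CTA)
    volumes: rigid NCCT-to-CTA co-registration, centerline-based localization
    of the contrast stop, paired circular-ROI mean Hounsfield-unit sampling at
    the occlusion site and the contralateral artery, and the derived metrics
    (attenuation increase, void fraction, and the CTA-index asymmetry
    measure). Includes synthetic CT phantom and cohort simulators with known
    ground truth, the cohort statistical battery (Wilcoxon rank-sum,
    residualized Spearman correlation, covariate-adjusted logistic regression,
    partial correlation, two-way random-effects ICC with confidence interval,
    exclusion filtering), and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
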