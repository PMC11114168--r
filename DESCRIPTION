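Package: vaeeg
Title: EEG Band-Power Comparison of Manual and Virtual Acupuncture Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16-channel scalp EEG recorded during manual
    and virtual (VR-presented) acupuncture sessions. Provides a synthetic EEG
    session generator with band-structured oscillations, 1/f background noise
    and frontally-weighted eye-blink artifacts; zero-phase FIR bandpass
    filtering and seeded fixed-point ICA with automated blink-component
    scoring; non-overlapping 2-second segmentation with a channel-weighted
    frequency-power summation statistic computed per segment and per channel;
    Kolmogorov-Smirnov normality screening and an exact/approximate
    Mann-Whitney U comparison plan between pooled and individual treatment
    events; and consistency/similarity aggregation of significance decisions,
    including reproduction of the published per-subject p-value table
    aggregates from packaged fixtures. EDF and CSV recording interchange are
    supported.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
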