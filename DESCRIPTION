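Package: extrawatch
Title: Real-Time Detection of Radiopharmaceutical Extravasation and SUV
    Correction from Dual-Arm Dose-Rate Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises extravasation events during
    intravenous administration of 18F-FDG from paired dose-rate time
    series recorded by wearable detectors on the injection and
    contralateral arms.  Implements peak-anchored windowing and Gaussian
    smoothing of the curves, the injection metrics (peak dose rate,
    plateau mean, normalised peak drop and arm-difference series),
    logistic threshold classification of administrations into normal,
    abnormal and extravasation classes, sphere-model dosimetry of the
    residual activity at the injection site, and a multiplicative
    correction coefficient for the standardised uptake value (SUV).
    A seeded synthetic-data generator emulates the three administration
    classes so the whole pipeline is testable without patient data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
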