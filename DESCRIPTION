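Package: operantVar
Title: Behavioral and Neural Variability Analysis for Fast Operant
    Lever-Pressing Tasks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for operant lever-pressing experiments in
    which reinforcement depends on a covert minimum-frequency target
    (three consecutive inter-press intervals summing below a bound).
    Segments press streams into bouts, computes per-sequence frequency,
    duration and length, evaluates covert-target hits and reinforcement,
    and quantifies trial-to-trial variability of behavioral features and
    of simultaneously recorded single-unit firing rates with variance and
    Fano-factor statistics, including sliding-window Fano traces.
    Includes peri-event time histogram construction with consecutive-bin
    modulation detection, cross-session unit stability assessment via
    pooled principal components, behavior-neural variability coupling
    with Fisher-z pooled Pearson correlations, percentile bootstrap
    inference for group differences, and a synthetic-data generator with
    known ground truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, graphics, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
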