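Package: vdtblink
Title: Automatic Blink Analysis for Visual-Display-Terminal Fatigue Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects eye blinks in facial-landmark streams via the eye aspect
    ratio (EAR), classifies blinks as complete or incomplete from eye-region
    images using a single-scale-retinex / magnification / binarization /
    contour chain and a subject-specific eyelid-descent calibration, extracts
    seven phase-wise blink features (blink number, mean blink interval, mean
    blink duration, group blink number and interval, incomplete blink number
    and interval), and analyses their progression across session phases with
    Friedman and Wilcoxon signed-rank tests. Includes a ground-truthed
    synthetic session generator (eyelid kinematics, landmark streams,
    rendered eye images) so the whole pipeline is testable without face
    recordings, plus command-line style entry points for simulation,
    detection and analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
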