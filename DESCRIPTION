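Package: swimtag
Title: Swim-Tunnel Respirometry and Biologging Energetics for Salmonids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for heart-rate and acceleration biologging of
    swimming fish under steady and unsteady (sinusoidally modulated) flow.
    Computes mass-specific oxygen consumption (MO2), cost of transport, optimal
    and critical swimming speeds from intermittent-flow respirometry traces;
    detects R-peaks and estimates heart rate with a four-level quality index
    from short ECG bursts; separates static and dynamic acceleration to derive
    external acceleration, its variance (VAR) and overall dynamic body
    acceleration (ODBA) from triaxial streams; generates and fits sinusoidal
    flow profiles; fits linear speed/activity/metabolism calibrations and
    transfers them to predict free-swimming energetics; and fits
    random-intercept mixed models to sentinel-fish circadian telemetry.
    Includes seeded synthetic-data generators for every input stream so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
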