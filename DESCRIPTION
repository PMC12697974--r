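Package: gemaflow
Title: Streaming Geofence Evaluation and Prompt Scheduling for Geographic
    Ecological Momentary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open engine for geographic ecological momentary assessment
    (GEMA) studies: streaming evaluation of GNSS location fixes against
    complex geofence polygons (concave, multi-part, holed), a declarative
    prompt scheduler with time-, location-, and response-contingent rules
    and one-hour expiry, reversible keyed coordinate masking for location
    privacy, a synthetic cohort simulator with motion-gated two-minute
    sampling, and adherence/latency/time-use analytics including WHO-5 and
    PROMIS Sleep Disturbance scale scoring. All user-facing functions take
    data frames first and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
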