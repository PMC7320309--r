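Package: portalog
Title: Session-Level Usage Metrics from Patient-Portal Audit Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts raw outpatient-portal audit log exports into validated
    session-level and patient-level usage metrics. Implements canonical
    record ordering, data-driven estimation of the inactivity threshold that
    bounds a coherent session, sessionization superseding unreliable
    server-assigned session numbers, device-type inference from user-agent
    strings, a configurable two-level taxonomy mapping raw action types to
    portal functions, correction of server keep-alive log-out and mobile
    duplicate-burst artifacts, and frequency and comprehensiveness-of-use
    metrics at the session and patient level. Includes a synthetic-cohort
    generator with ground truth for end-to-end validation and a command-line
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
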