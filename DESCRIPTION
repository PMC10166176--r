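Package: seqpsm
Title: Treatment-Sequencing Partitioned Survival Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state partitioned survival model (first line, second
    line and beyond, death) for comparing treatment sequences in
    transplant-ineligible newly diagnosed multiple myeloma. Fits parametric
    survival distributions to right-censored time-to-next-treatment and
    second-line overall-survival data, derives comparator arms by
    proportional-hazards transforms, applies fixed attrition between lines
    of therapy, adjusts for general-population mortality via a life table,
    and quantifies uncertainty with probabilistic sensitivity analysis.
    Includes a synthetic pseudo individual-patient-data generator so the
    full pipeline is testable without access to trial or registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    flexsurv,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
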