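Package: migtensor
Title: Spatio-Temporal Tensor Co-Clustering of Migration Flow Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers stable migration systems in origin-by-destination-by-time
    flow count data via a diagonal-masked nonnegative canonical polyadic (CP)
    tensor decomposition. Each rank-one component is a migration system: a
    sparse set of origin geographies, a sparse set of destination geographies,
    and a temporal intensity profile. Provides tensor construction from
    long-format flow records, an EM/HALS solver for the masked nonnegative
    least-squares objective, rank-selection and stability diagnostics, system
    extraction (memberships, probabilities, top-k lists, association matrices,
    temporal shock detection, whole-region classification), a planted-system
    synthetic generator with factor-recovery scoring, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
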