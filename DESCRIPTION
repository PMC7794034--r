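Package: autoregkit
Title: Static, Pseudo-Dynamic and Dynamic Cerebral Autoregulation Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing cerebral autoregulation (CA) from multimodal
    pressure and blood-flow recordings. Implements the three classical CA
    assessment families on a common preprocessing backbone: static CA via
    reconstruction of Lassen's curve (cerebral blood-flow change over 1 mmHg
    cerebral perfusion pressure bins, with plateau/limit estimation),
    pseudo-dynamic CA via the pressure reactivity index (PRx; moving-window
    Pearson correlation of slow arterial and intracranial pressure, averaged
    per perfusion-pressure group through Fisher's Z), and dynamic CA via the
    phase lag between arterial and intracranial pressure at induced
    oscillation frequencies (equiripple narrowband filtering and
    analytic-signal phase extraction). A seeded lumped-parameter
    cerebrovascular simulator with a tunable autoregulation state generates
    complete synthetic study recordings, including oscillation protocols and
    optical blood-flow-index quality artifacts, so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
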