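Package: nitroforage
Title: Compartmental Model of Preferential Root Nitrate Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates root system growth under heterogeneous soil nitrate as a
    compartmental ordinary differential equation model. Root length growth in
    each compartment is coupled to local and systemic nitrate pools, CEP
    peptide demand signalling, cytokinin supply signalling, local nitrate
    stimulation, systemic survival/foraging/repression responses and
    sink-strength carbon allocation, each entering the growth rate as a
    multiplicative Hill-type regulatory factor. Provides single-root
    dose-response, split-root and nitrate-patch experiment runners, in-silico
    mutants (nrt1.1, cep, ck), closed-form pool steady states, the analytic
    exponential-growth solution used for calibration, and the dry-weight to
    per-millimetre nitrate unit-conversion chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
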