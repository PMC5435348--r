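Package: cyclosim
Title: Cohort-Based Cell-Cycle Simulation of Checkpoint-Targeted Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort simulator of asynchronous cell populations
    progressing through a 63-compartment cell-cycle state structure, coupled to
    kinetic models of the G1-S restriction checkpoint (cyclin D/cdk4, cyclin
    E/cdk2, RB, E2F), the spindle assembly checkpoint (kinetochore attachment
    dynamics and an aurora-kinase-sensitive wait signal), EGF/MAP-kinase
    signalling and a caspase-cascade apoptosis module.  Hill-equation
    pharmacodynamics for four drug mechanism classes (non-cycle-specific kill,
    S-phase kill, mitotic arrest, cdk4/6 inhibition) allow normal and
    checkpoint-deficient cell lines to be compared under drug combinations and
    schedules, including dose-response surfaces with Bliss-independence
    interaction scores and inter-drug delay scans for cyclotherapy design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
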