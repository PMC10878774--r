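Package: poreflux
Title: Electroporation Pore Dynamics and Transmembrane Cisplatin Uptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a phenomenological two-state pore model of cell
    membrane electroporation driven by arbitrary trains of rectangular
    electric pulses (monopolar, millisecond, nanosecond and high-frequency
    bipolar burst protocols), and predicts the resulting diffusive uptake
    of small molecules such as cisplatin in molecules per cell. Provides a
    hybrid stiff-ODE/closed-form integrator for long post-pulse horizons,
    hindered-diffusion (Renkin) permeability calculations, data-reduction
    utilities for ICP-MS platinum and clonogenic-survival measurements,
    and a synthetic-measurement generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
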