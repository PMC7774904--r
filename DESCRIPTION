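Package: turingov
Title: Self-Organising Turing Patterning of the Optic Vesicle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a Pax6/Follistatin/Tgfb2
    activator-inhibitor reaction-diffusion network proposed to polarise the
    vertebrate optic vesicle. Provides the reaction kinetics
    (ligand-antagonist sequestration, receptor activation, Pax6
    autoregulation and its inhibition by Tgfb signalling and by a static
    Shh gradient), method-of-lines integration on 1D grids and masked 2D
    explant-shaped domains with zero-flux or periodic boundaries, linear
    stability analysis (dispersion relation, Turing and wave-instability
    classification, dominant-wavelength prediction), scenario generators
    for de-novo patterning, explant repolarisation, morphogen-gradient
    orientation and loss-of-function experiments, and pattern metrics
    (pole counting, polarisation index, phase correlation, oscillation
    detection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
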