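Package: biofilmmech
Title: Mechanical Analysis of Dental Biofilm Detachment, Stiffness and
    Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the mechanical destabilisation of oral biofilms by
    antibacterial treatments. Implements rotating-disc rheometry detachment
    analysis (biofilm momentum coefficient, torque-curve area, detachment
    events and the critical detachment shear stress), uniaxial flat-probe
    indentation analysis (contact and substratum detection, thickness,
    stress-strain transformation and Young's modulus), a modified
    fractional-inhibitory-concentration interaction index for two-agent
    treatments, and COMSTAT-style quantification of two-channel confocal
    stacks (biomass and roughness coefficient). A seeded synthetic-data
    generator emulates the instruments and treatment-group effects so every
    stage is testable against known ground truth, and a pipeline driver runs
    the full study with one-way ANOVA and Tukey post hoc group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
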