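Package: memfield
Title: Mean-Field Membrane Electrostatics, Trajectory Analytics and
    Sterol-Transfer Kinetics for Peripheral Proteins
Version: 1.0.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how soluble lipid-transfer proteins such as
    StarD4 engage anionic membranes.  Implements a linearized
    Poisson-Boltzmann mean-field model of a fixed-charge protein adsorbing
    onto a planar membrane whose anionic lipids (e.g. PS or PIP2) are
    laterally mobile and redistribute self-consistently against their mixing
    entropy; an orientation scan that ranks protein poses by adsorption free
    energy and exports steady-state lipid density maps; trajectory analytics
    for membrane-bound proteins (helix tilt and rotation orientation maps,
    residue-lipid contact probabilities and multiplicities, buried
    contact-area membrane-embedding detection); single-exponential FRET
    fitting with conversion to sterol molecules transferred per protein per
    minute; and seeded synthetic-data generators (bead proteins, lattice
    bilayers, planted trajectories, noisy FRET traces) so the full pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
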