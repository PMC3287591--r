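Package: aquaperm
Title: Single-Channel Water Permeability Analysis for Membrane Channel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium molecular-dynamics analysis of water transport through
    membrane channels such as aquaporins. Counts complete water permeation
    events to obtain the diffusive single-channel permeability p_d, estimates
    the osmotic permeability p_f with the collective diffusion model (the
    dimensionless collective coordinate n(t), its multi-origin mean-square
    displacement and the fitted collective diffusion constant D_n), and
    reports the p_f/p_d "single-fileness" ratio, channel water occupancy,
    HOLE-style pore radius profiles, water dipole order parameters P1(z) and
    P2(z), and basic structural metrics (RMSD, RMSF, average structures).
    Includes an event-driven single-file channel simulator with known
    transport parameters so every estimator can be validated against ground
    truth without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
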