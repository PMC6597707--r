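Package: ceimig
Title: Coulomb Explosion Imaging Analysis of Hydrogen Migration in Ethanol Ions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved single and double hydrogen
    migration in ethanol cations and dications observed by pump-probe Coulomb
    explosion imaging. Provides a classical point-charge breakup simulator for
    concerted and sequential fragmentation, per-event kinematics (kinetic
    energy release, Newton-frame momenta, Dalitz coordinates), an idealized
    ion-momentum spectrometer forward/inverse model with PIPICO-style
    coincidence gating, delay-dependent yield extraction, and migration-time /
    bond-break analysis of molecular-dynamics-style trajectory ensembles,
    together with a synthetic-data generator emulating both the coincidence
    event streams and the trajectory ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
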