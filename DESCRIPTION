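Package: perisurf
Title: Areal Surface Texture Analysis and Biomimetic Substratum Design for
    Periphyton Colonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse engineering and testing algal-colonization
    substrata from profilometer height maps. Computes the areal surface
    texture parameter families of ISO 25178-2 (height, functional, spatial,
    volumetric, stratified and feature parameters) including the areal
    material ratio (Abbott-Firestone) curve; segments surfaces into hills
    and dales by watershed with Wolf pruning at a fraction of the maximum
    surface height; screens parameters between colonized and bare features;
    synthesizes pseudo-random surfaces with targeted Sa, Sv and Smr values
    using the Pearson distribution system with spatial correlation and
    micro-patterned depressions; validates synthesis fidelity; and analyzes
    periphyton colonization outcomes (biomass ANOVA with Tukey lane checks
    and Anderson-Darling normality, hill-localization of early colonization
    sites). Includes seeded synthetic-data generators emulating rock-like
    surfaces, per-feature parameter tables, biomass datasets and
    colonization site maps so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
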