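Package: matriline
Title: Colony Genetic Structure and Caste Morphometrics for Social Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the genetic structure of social wasp
    colonies from codominant microsatellite genotypes under haplodiploid
    inheritance: detection of drifted workers, partitioning of offspring into
    matrilines, inference of queen and paternal genotypes by allele
    subtraction, queen mating-frequency estimation, and the analytic
    non-detection and non-sampling error probabilities attached to those
    inferences. Also provides landmark-based caste discrimination for wing
    morphometrics (generalized Procrustes superimposition, Procrustes ANOVA
    with residual-randomization permutation, common allometric component,
    shape PCA, size-gap caste splitting), simple nest-census arithmetic, and
    Mendelian colony and wing-shape simulators with ground truth for
    validating every inference step. Ships the published microsatellite
    allele frequencies and nest census tables for the giant hornet Vespa
    soror as worked inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
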