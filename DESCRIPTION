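Package: stabarch
Title: Genetic Architecture of Quantitative Traits Under Pleiotropic
    Stabilizing Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the genetic architecture of a quantitative trait that
    evolves under stabilizing selection in a multidimensional (pleiotropic)
    trait space. Computes diffusion sojourn-time densities for the
    underdominant allelic dynamic, the expected per-site contribution to
    additive genetic variance as a function of the scaled selection
    coefficient, minor-allele-frequency decompositions, and the distribution
    of variances among segregating sites G(v), with closed forms in the
    strong-selection and effectively-neutral regimes validated against a
    numeric oracle. Includes a Wright-Fisher forward simulator of per-site
    trajectories under piecewise demography, an individual-based multilocus
    validator, a synthetic-GWAS generator, and a one-parameter maximum
    likelihood fit of the strongly selected variance scale v_s to tables of
    genome-wide significant associations, with mutational target size,
    detectable-fraction estimates, and heritability-versus-study-size
    projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
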