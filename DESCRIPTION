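Package: pollenflow
Title: Hierarchical Pollen Pool Differentiation from Mother-Seed Genotype Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-generation (TwoGener) analysis of pollen-mediated gene flow
    from codominant mother-seed microsatellite genotype tables. Infers haploid
    paternal gametes by subtracting the maternal contribution (resolving
    ambiguous heterozygote pairs via posterior gametic likelihoods), quantifies
    hierarchical pollen pool differentiation among sites and among mothers
    within sites with nested AMOVA Phi-statistics on unbalanced designs, and
    tests significance with stratified permutation tests. Includes
    paternity-adjacent statistics (probability of identity, paternity exclusion
    probability, an exclusion/likelihood selfing classifier), seed-filtering
    model constructions controlling for selfing and within-fruit correlated
    paternity, a hierarchical Dirichlet (Balding-Nichols) synthetic-data
    generator, and a Monte Carlo harness estimating type-I error and power of
    the permutation tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'genotype-io.R'
    'gamete-inference.R'
    'amova.R'
    'mating.R'
    'simulate.R'
    'harness.R'
    'pipeline.R'
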