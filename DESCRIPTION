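Package: cryptomorph
Title: Genotype-Phenotype Analysis of a Polymorphic Moth Under Different Visual Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the inheritance and visual discriminability of a
    Mendelian one-locus two-allele colour polymorphism, modelled on the wood
    tiger moth (Arctia plantaginis) hindwing system. Provides a seeded
    synthetic-data generator for pedigrees and multichannel (uv/sw/mw/lw)
    specimen images; chi-square segregation testing and exact pedigree
    back-trace of parental genotypes from offspring phenotype ratios;
    granularity (Fourier band-pass) pattern metrics, colour and allometry
    feature extraction with correlation filtering; linear discriminant
    classification of genotypes with shadow-feature (random forest)
    importance screening; and receptor-noise-limited chromatic contrast (dS)
    modelling for human, avian and moth receivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
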