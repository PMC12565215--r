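Package: mycoGraze
Title: Macrofungal Community Survey Analysis for Grazing Impact Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing nested quadrat surveys of macrofungal
    communities under silvopasture (forest grazing) disturbance. Provides a
    validated data model for subquadrat-level species records with
    distance-based sporocarp-to-individual coding, Simpson/Pielou/Margalef
    diversity indices, Mann-Whitney comparisons with Cliff's delta effect
    sizes and magnitude banding, a dominance (importance-value) index over
    species and trait partitions, principal component analysis linking
    diversity to litterfall and coarse plant-remains covariates, spore
    morphometric range notation, and a seeded synthetic-survey generator
    for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
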