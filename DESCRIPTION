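Package: fruitsignals
Title: Colour-Odour Signal Trade-Offs in Wild Fruit Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trade-offs between chromatic and olfactory
    fruit signals in a community of fleshy-fruited plants. Computes derived
    fruit traits (ellipsoid surface area, surface-area-scaled volatile
    organic compound index, brightness-normalized reflectance band
    proportions, peak hue and brightness), screens trait associations with
    Pearson correlations, fits a natural-cubic-spline regression of odour on
    the full reflectance spectrum with delta-method band effects, and tests
    phylogenetic signal of every trait (continuous-character parsimony with
    consistency and retention indices, Blomberg's K, Pagel's lambda) on a
    framework tree built from taxonomy. A synthetic-community generator with
    injectable colour-odour effects supports calibration and recovery
    testing. Ships the published 56-species Malagasy dry-forest trait table
    as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
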