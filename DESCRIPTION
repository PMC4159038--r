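Package: eihe
Title: Ecological Index of Hydrocarbon Exposure from 16S rRNA Amplicon Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the ecological index of hydrocarbon exposure (EIHE), a
    guild-sum indicator over genus-level 16S rRNA amplicon taxonomy tables:
    the summed relative abundance (percent of total reads) of a curated set
    of 63 bacterial genera linked to hydrocarbon biodegradation. Parses
    mothur-style hierarchical taxonomy summaries and generic genus count
    matrices, ships a replaceable default guild definition, and implements
    the accompanying statistical toolkit (Fisher's exact two-proportion test
    with Newcombe-Wilson hybrid score confidence intervals, Welch's t,
    Kruskal-Wallis with Dunn post-hoc comparisons), alpha-diversity
    reporting (Good's coverage, Chao1 and Shannon with confidence intervals,
    subsampling to a fixed depth), and a Dirichlet-multinomial community
    simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
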