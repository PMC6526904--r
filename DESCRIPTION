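Package: clanshield
Title: Hidden-Paralog Screening for Single-Copy Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hidden paralogy in putatively single-copy gene families by
    testing a priori "incontestable" taxon groups (clans, in the unrooted sense)
    against per-family gene trees, and removes families that cannot recover one
    or more of those groups. Provides the unrooted split/clan primitives, exact
    enumeration of the worst-case late-loss retention combinations after ancient
    gene duplications, gene-tree simulators under the multispecies coalescent
    and under early-duplication plus late-loss models for validating the filter,
    and alignment-level screens for substitution saturation and compositional
    heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
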