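Package: polyAcomp
Title: Poly(A) Site Mapping and 3'UTR/3'COR Base-Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps polyadenylation (poly(A)) sites by exact, zero-mismatch
    placement of poly(A)-tailed transcript anchors on a reference genome and
    characterises the base composition of the 3' untranslated region (3'UTR)
    and the pre-mRNA 3' cleaved-off region (3'COR) around each cleavage
    junction. Provides per-position composition metaprofiles, window
    compositions, region/genome ratios and U/A ratios; internal-priming
    artifact flagging via downstream genomic A-runs; group-comparison
    statistics (one-way ANOVA, Duncan's multiple range test with letter
    display, equal-variance t-test, 2x2 chi-square); and a seeded synthetic
    genome/transcript simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
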