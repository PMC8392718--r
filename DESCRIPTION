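Package: gfabric
Title: Genomic Fabric Analysis of Replicated Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises every gene of a replicated transcriptome by three
    independent measures - average expression level (AVE), chi-square
    interval-corrected relative expression variability (REV) and pairwise
    expression correlation (COR) - and derives from them the Gene Commanding
    Height (GCH) hierarchy, composite differential-expression calls with
    variability-adjusted fold-change cutoffs, weighted individual and pathway
    regulation scores (WIR/WPR), signed coordination networks and cross-region
    expression synchrony.  Includes a seeded spot-level microarray simulator
    emulating a two-region, three-phenotype, four-replicate design with
    redundant probes, corrupted and low-signal spots, co-regulation blocks and
    paired animals, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
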