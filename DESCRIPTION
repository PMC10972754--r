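Package: bgcprior
Title: Candidate Gene Prioritization for Plant Biosynthetic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks genome-wide candidate genes for missing steps of a plant
    specialized-metabolite pathway by combining three evidence channels: Pearson
    correlation of expression with a characterized bait gene across multi-tissue
    RNA-seq, absolute transcript abundance (TPM) in the tissue where the pathway
    is most active, and membership in putative biosynthetic gene clusters called
    from genomic proximity of signature enzyme classes. Each channel is mapped
    onto a piecewise-linear sub-score in [0, 1] (the cluster channel onto
    {0, 0.5, 1}) and summed into a composite score with a maximum of 3.0.
    Includes a synthetic genome and count-matrix simulator with a planted,
    primordium-enriched, partially genome-clustered pathway module so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
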