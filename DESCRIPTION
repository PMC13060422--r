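Package: rmdskit
Title: Regional Motif Diversity Scores for Cell-Free DNA Fragmentomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the regional motif diversity score (rMDS), a per-bin
    normalized Shannon entropy of cell-free DNA fragment 5' end k-mer motifs,
    and provides the surrounding analysis pipeline: fragment quality filtering,
    end-motif extraction from a reference genome, a 3' end composition control,
    response-preserving linear batch correction with frozen coefficients,
    empirical-Bayes moderated differential testing with patient blocking,
    trajectory clustering of differential bins, telomere-proximity enrichment
    against a random-bin null, sequencing-depth stability analysis, and
    patient-level treatment-response classification under patient-grouped
    validation schemes. A built-in synthetic cohort simulator generates toy
    reference genomes and longitudinal multi-institute fragment cohorts with
    planted regional entropy differences for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    glmnet,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    limma,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
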