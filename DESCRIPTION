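Package: phylotraits
Title: Ranking Gene Families by Their Association with a Binary Genomic Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for ranking gene families (enzyme EC numbers and Pfam
    domains, by genome copy number) according to their association with the
    acquisition of a binary genomic trait such as the Calvin cycle. Stages:
    trait calling from profile-HMM marker hits, greedy closest-relative
    case-control pairing, Wilcoxon enrichment with Benjamini-Hochberg control,
    ancestral character estimation on similarity-selected subtrees (2-state
    Mk trait likelihoods, Brownian-motion ancestral copy numbers) summarized
    by a q-value-weighted sum of absolute Spearman correlations, random-forest
    importance ranking with recursive feature elimination, consensus rank
    aggregation, and gene-neighbourhood proximity analysis. A synthetic-data
    generator (pure-birth trees, Markov binary traits, Brownian-Poisson copy
    numbers, operon-like ORF layouts) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    Biostrings,
    glmnet,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
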