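Package: ltspevo
Title: Lineage Structure, Selection and Historical Contingency in
    Long-Term Stationary Phase Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for clone-resolved whole-genome mutation
    tables from long-term stationary phase (LTSP) evolution experiments.
    Reads per-clone called-mutation tables and a genome annotation,
    reconstructs clonal lineages within each population from
    Levenshtein distances between mutation profiles, computes
    convergence and dN/dS selection statistics with per-site
    synonymous/nonsynonymous site counting, screens pairs of
    convergently mutated loci for putative historical contingency with
    Yule's Q, Y and phi association coefficients (one-sided tests with
    Benjamini-Hochberg correction), infers the directionality of
    contingencies from ancestor-descendant chains, and tests functional
    enrichment of contingent pairs by randomization.  Includes a seeded
    simulator of LTSP-like clone samples with planted lineages,
    mutators, convergent loci and contingent loci pairs, with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
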