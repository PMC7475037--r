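Package: introscan
Title: Characterizing Introgressed Archaic Haplotypes and Mobile-Element
    Insertions from Low-Coverage Ancient DNA
Version: 0.1.0
Authors@R:
    person("introscan", "developers", email = "introscan@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse archaic (e.g. Neandertal) haplotypes that
    introgressed into modern human populations.  The package genotypes a
    polymorphic mobile-element (Alu) insertion in short ancient-DNA shotgun
    fragments using coverage-drop statistics and junction/spanning fragment
    counts, characterizes introgressed haplotypes in phased panels
    (per-population allele frequencies, pairwise r-squared, lineage-private
    SNPs, r-squared-defined segment extent, archaic-match matrices),
    computes the probability that a shared haplotype of a given length is
    explained by incomplete lineage sorting rather than admixture, and
    post-processes association summary statistics (Wald odds-ratio
    confidence intervals, family-wise error-rate adjustment).  A
    synthetic-data module generates phased haplotype panels with planted
    introgressed segments, archaic diploid genotypes, and ancient-DNA
    fragment sets with recorded ground truth, so the whole pipeline is
    exercisable and testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    stringi,
    utils
Suggests:
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
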