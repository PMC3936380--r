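Package: phylorefugia
Title: Chloroplast Phylogeography: Haplotype Networks, AMOVA/SAMOVA,
    Demographic Tests and Coalescent Hypothesis Testing of Refugia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-locus (chloroplast) phylogeographic analysis:
    collapsing aligned sequences into haplotypes with configurable gap
    handling, statistical-parsimony haplotype networks with a 95% connection
    limit, population diversity and differentiation statistics (haplotype and
    nucleotide diversity, pairwise Phi-ST, Pons-Petit ordered/unordered
    G_ST and N_ST with a permutation test for phylogeographic signal),
    hierarchical analysis of molecular variance with permutation tests and a
    spatial (simulated-annealing) search for geographically contiguous
    population groups, neutrality tests (Tajima's D, Fu's Fs) and
    mismatch-distribution analysis under the sudden-expansion model,
    demographic unit conversions for isolation-with-migration output,
    structured-coalescent simulation of gene genealogies with the
    Slatkin-Maddison s statistic for testing refugial scenarios, and
    background-corrected tests of ecological niche divergence versus
    conservatism.  Includes a synthetic-data generator so every analysis
    stage can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    MASS,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
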