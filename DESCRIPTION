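Package: trfscreen
Title: Thermodynamic Screening of tRNA-Derived Fragments Against mRNA Target Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising small-RNA silencers
    derived from tRNAs (tRFs). Builds candidate 5'/3' terminal fragments from
    tRNA sequences, scores tRF:target-site hybrids by nearest-neighbor
    intermolecular minimum free energy (Turner 2004 stacking parameters, G.U
    wobbles, bulge and internal loops; no intramolecular structure), scans a
    3'UTR for binding sites, and ranks hits by free energy and
    complementarity. Downstream characterisation of a knockdown is covered by
    TPM normalisation, per-gene Welch tests at configurable log2
    fold-change/p thresholds, hierarchical bi-clustering, a weighted
    Kolmogorov-Smirnov gene-set enrichment score with permutation p-values,
    hypergeometric over-representation, four-parameter logistic IC50 fitting
    with bootstrap intervals, 2^-ddCt quantification, wound-healing rate and
    caliper tumor-volume summaries. Seeded generators produce every input the
    pipeline consumes (tRNA libraries, UTRs with planted binding sites,
    negative-binomial count matrices with planted differential genes and a
    down-shifted pathway, dose-response, qPCR and tumor-growth tables) so the
    whole chain runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
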