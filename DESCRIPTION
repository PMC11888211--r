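Package: vchimera
Title: Hidden Markov Model Detection of PCR Chimeras in AIRR-seq V Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects PCR-generated chimeric V(D)J rearrangements in adaptive
    immune receptor repertoire sequencing (AIRR-seq) data. Each query,
    pre-aligned to its closest germline V allele, is threaded onto a multiple
    sequence alignment of the germline V database and scored with a hidden
    Markov model whose states pair every reference with a mutation-rate class
    and a chimeric/non-chimeric label. The Forward algorithm yields the
    posterior probability that the query is a template-switch product of two
    or more references, and the Viterbi algorithm reports parent segments and
    breakpoints. Includes a discretized mutation-rate mode, a Baum-Welch mode
    that fits continuous per-reference mutation rates, and a simulation and
    evaluation framework for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
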