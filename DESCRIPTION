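Package: pedphase
Title: Minimum-Recombination Haplotype Phasing on General Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers haplotypes for every member of a general pedigree from SNP
    genotype data while minimizing the number of recombination events (the
    minimum-recombination haplotype configuration problem). The pedigree is
    compiled into a colored signed graph whose line index equals the minimum
    recombination count; that problem is in turn reduced to graph bipartization
    by edge removal with per-member parity constraints and solved exactly by an
    iterative-compression fixed-parameter algorithm using Edmonds-Karp maximum
    flows and the Picard-Queyranne closure structure of all minimum cuts.
    Includes LINKAGE/PED-style input parsing, Mendelian consistency checking,
    brute-force reference oracles, and a pedigree simulator with planted
    recombination breakpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
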