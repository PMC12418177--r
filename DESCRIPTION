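Package: aracna
Title: Allele-Specific Somatic Copy Number Calling with Long-Range Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tumour-only somatic copy number alteration (CNA) calling from
    per-SNP read depth and B-allele frequency tracks. Implements a generative
    forward model linking allele-specific copy numbers, tumour purity and read
    depth per copy to observed data; a seeded simulator of supervised training
    genomes; a bidirectional long-range sequence-labelling network trained by
    curriculum on simulations only; a transition-penalised Viterbi-style
    smoother; zero-shot calling of purity, ploidy, whole-genome duplication and
    segment profiles; and reconstruction/concordance metrics including a
    Battenberg-style multiclonal reconstruction. All components run at desk
    scale on a single CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
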