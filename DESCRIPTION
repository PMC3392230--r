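Package: radsexscan
Title: Sex-Association Genome Scans for RAD-Sequenced F2 Intercrosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping sex-associated regions in F2 intercross
    families genotyped by restriction-site associated DNA (RAD) sequencing.
    Implements a maximum-likelihood diploid genotype caller with a bounded
    uniform prior on the per-nucleotide sequencing error rate and a
    likelihood-ratio call criterion; a per-SNP G-test scan of genetic
    differentiation between males and females with Benjamini-Hochberg false
    discovery rate control; a binary-trait single-marker LOD scan on
    phase-known four-way genotypes with genome-wide permutation thresholds,
    1.5-LOD support intervals and haplotype-by-sex tables; sex-specific
    recombination-fraction estimation with Kosambi map conversion and
    sliding-window cM/Mb rate profiles; genomic-element region enrichment
    summaries; and a forward simulator of reciprocal F2 crosses with
    sex-specific maps, penetrance-based sex determination and multinomial
    read counts, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
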