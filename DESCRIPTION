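Package: phasefilt
Title: Consistency-Based Filtering of Small Variants for Long-Read Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters heterozygous small variants (in particular INDELs called
    from noisy nanopore long reads) by how consistently their alleles
    co-segregate with neighboring variants across reads. Each read is tagged
    with a 0/1 allele at every heterozygous site it covers (an extractHAIRS-style
    fragment extraction from BAM, or a HapCUT2 fragment file can be supplied);
    every nearby site pair is scored by max(x, y)/(x + y) over the reads
    covering both, where x counts discordant (01/10) and y concordant (00/11)
    allele patterns; a three-step threshold strategy with a variant-quality
    fallback removes low-consistency sites and writes a filtered VCF for
    downstream phasing. Includes a truth-labeled diploid read simulator and an
    evaluation harness (precision/recall, a greedy reference phaser, switch
    errors, phase-block N50, and a threshold grid search).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rsamtools,
    Biostrings,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
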