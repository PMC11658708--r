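Package: meiorec
Title: Genome-Wide Mapping of Meiotic Recombination Events from Tetrad and
    Octad Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls and classifies meiotic crossover (CO) and noncrossover
    (NCO) recombination events genome-wide from per-marker allele counts in
    sequenced tetrads and octads of a hybrid Saccharomyces cerevisiae cross.
    Converts pileup-style allele counts into binary parental genotype calls,
    reconstructs heteroduplex DNA (hDNA) information in mismatch-repair
    deficient backgrounds (including pseudo-octads built from tetrad colonies
    and strand phasing from resequenced colonies), segments chromosomes into
    segregation patterns (4:4, 5:3, 6:2, 6:2*, 4:4*, 7:1, 8:0, ...), groups
    non-Mendelian segments into recombination events, and assigns events to
    multi-DSB, trans-DSB, and strand-transfer subcategories.  Provides the
    accompanying spatial statistics: Monte-Carlo simulation of non-exchange
    (crossover-less) chromosomes under length-proportional random allocation,
    inter-crossover distance gamma modelling of crossover interference,
    event mid-length tract estimates, crossover homeostasis trends,
    telomere/centromere distance distributions, and standard hypothesis tests
    with Benjamini-Hochberg correction.  A synthetic-meiosis simulator with
    known ground truth generates marker maps, strand matrices and read counts
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
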